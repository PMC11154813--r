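# Synthetic cohort generator. Emulates the study conditions the analysis
# modules are built for: a tinnitus group (n = 21) and a matched control
# group (n = 26), four noise-vocoded listening conditions (6 or 16 vocoder
# channels at the individual 50% or 80% SRT), 90 six-second trials per
# condition, simultaneous EEG (parietal 10 Hz alpha amplitude modulated
# between the noise baseline and the sentence-encoding phase, on a pink-
# noise background) and pupillometry (slow-drifting ~1000 px diameter with
# a smooth task-evoked dilation peak, blinks, and sensor noise). Subject-
# level true effect sizes are drawn from group normal distributions whose
# means and SDs are the package's reference cohort parameters.

#' Listening-condition labels
#' @return The four condition labels.
#' @export
listening_conditions <- function() {
  c("6ch50% SRT", "16ch50% SRT", "6ch80% SRT", "16ch80% SRT")
}

#' Default synthetic-cohort specification
#'
#' Group sizes, per-condition group means/SDs of the EEG alpha-power change
#' and of the MPD percent change, SRT distributions, THI scores, MoCA
#' distributions, trial counts, and the physiological generator parameters.
#' All values can be overridden through [cohort_spec()].
#'
#' @return A list of class `cohort_spec`.
#' @export
default_cohort_spec <- function() {
  conditions <- listening_conditions()
  spec <- list(
    n_tinnitus = 21,
    n_control = 26,
    conditions = conditions,
    alpha_change = data.frame(
      condition = conditions,
      tinnitus_mean = c(113.92, 116.14, 88.50, 124.23),
      tinnitus_sd = c(84.26, 63.35, 41.54, 67.70),
      control_mean = c(183.60, 200.86, 174.66, 210.69),
      control_sd = c(61.01, 95.31, 78.38, 96.71),
      stringsAsFactors = FALSE),
    mpd = data.frame(
      condition = conditions,
      tinnitus_mean = c(9.1, 8.7, 9.6, 8.4),
      tinnitus_sd = c(0.3, 0.3, 0.3, 0.3),
      control_mean = c(10.7, 10.2, 10.5, 10.3),
      control_sd = c(0.3, 0.3, 0.4, 0.2),
      stringsAsFactors = FALSE),
    srt = data.frame(
      target = c(0.5, 0.8),
      tinnitus_mean = c(1.71, 2.41),
      tinnitus_sd = c(0.87, 0.82),
      control_mean = c(1.63, 2.37),
      control_sd = c(0.71, 0.64)),
    thi_scores = c(42, 44, 28, 38, 42, 34, 46, 36, 28, 40, 52,
                   44, 62, 46, 32, 26, 34, 42, 56, 28, 54),
    moca = data.frame(group = c("tinnitus", "control"),
                      mean = c(27.47, 28.04), sd = c(1.07, 0.97)),
    trials_per_condition = 90,
    n_warmup_trials = 5,
    sample_rate_hz = 1000,
    eeg = list(alpha_amp_uv = 12.5, noise_sd_uv = 5,
               trial_jitter_pct = 30, ramp_s = 0.4,
               channels = parietal_channels()),
    pupil = list(base_px = 1000, sensor_sd_px = 2, drift_px = 3,
                 blink_rate_hz = 0.2, trial_jitter_pct = 1.5,
                 onset_s = 1.2, peak_s = 3.0, shape = 10)
  )
  class(spec) <- "cohort_spec"
  spec
}

#' Build a cohort specification with overrides
#'
#' @param ... Named fields replacing entries of [default_cohort_spec()];
#'   nested lists (`eeg`, `pupil`) are merged element-wise.
#' @return A validated `cohort_spec`.
#' @export
cohort_spec <- function(...) {
  spec <- default_cohort_spec()
  dots <- list(...)
  for (nm in names(dots)) {
    if (nm %in% c("eeg", "pupil")) {
      spec[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      spec[[nm]] <- dots[[nm]]
    }
  }
  validate_cohort_spec(spec)
}

validate_cohort_spec <- function(spec) {
  if (spec$n_tinnitus < 2 || spec$n_control < 2)
    stop_invalid("group sizes must be at least 2")
  if (any(c(spec$alpha_change$tinnitus_sd, spec$alpha_change$control_sd,
            spec$mpd$tinnitus_sd, spec$mpd$control_sd) < 0))
    stop_invalid("SDs must be non-negative")
  if (spec$trials_per_condition <= spec$n_warmup_trials)
    stop_invalid("trials_per_condition must exceed n_warmup_trials")
  spec
}

#' Draw the latent per-subject truth table of a cohort
#'
#' Subject-level true values are normal draws from the group parameters:
#' per condition an alpha-change and an MPD percent change, plus SRTs
#' (`srt80` constrained >= `srt50`), a THI score (tinnitus group only; the
#' reference score set is used as-is when the group size matches, otherwise
#' resampled) and a MoCA score.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer master seed.
#' @return Data frame with one row per subject x condition: `subject`,
#'   `group`, `condition`, `alpha_true`, `mpd_true`, `srt50`, `srt80`,
#'   `thi`, `moca`.
#' @export
draw_cohort_truth <- function(spec = default_cohort_spec(), seed = 1) {
  with_seed(derive_seed(seed, "truth"), {
    rows <- list()
    for (group in c("tinnitus", "control")) {
      n <- if (group == "tinnitus") spec$n_tinnitus else spec$n_control
      pick <- function(df, col) df[[paste0(group, "_", col)]]
      srt50 <- stats::rnorm(n, spec$srt[[paste0(group, "_mean")]][1],
                            spec$srt[[paste0(group, "_sd")]][1])
      gap_mean <- spec$srt[[paste0(group, "_mean")]][2] -
        spec$srt[[paste0(group, "_mean")]][1]
      srt80 <- srt50 + abs(stats::rnorm(n, gap_mean, gap_mean / 3))
      thi <- if (group == "tinnitus") {
        if (n == length(spec$thi_scores)) spec$thi_scores
        else sample(spec$thi_scores, n, replace = TRUE)
      } else rep(NA_real_, n)
      mrow <- spec$moca[spec$moca$group == group, ]
      moca <- pmin(30, pmax(26, round(stats::rnorm(n, mrow$mean, mrow$sd))))
      for (ci in seq_along(spec$conditions)) {
        a_true <- stats::rnorm(n, pick(spec$alpha_change, "mean")[ci],
                               pick(spec$alpha_change, "sd")[ci])
        m_true <- stats::rnorm(n, pick(spec$mpd, "mean")[ci],
                               pick(spec$mpd, "sd")[ci])
        rows[[length(rows) + 1]] <- data.frame(
          subject = sprintf("%s%02d", toupper(substr(group, 1, 1)), seq_len(n)),
          group = group, condition = spec$conditions[ci],
          alpha_true = pmax(a_true, -99), mpd_true = pmax(m_true, -99),
          srt50 = srt50, srt80 = srt80, thi = thi, moca = moca,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

# Raised-cosine step from 0 to 1 centered at t0 with width w.
raised_cosine_step <- function(t, t0, w) {
  ifelse(t < t0 - w / 2, 0,
         ifelse(t > t0 + w / 2, 1, 0.5 * (1 + sin(pi * (t - t0) / w))))
}

#' Synthesize a block of EEG trials with a known alpha-power change
#'
#' Generates a continuous recording of `n_trials` consecutive 6-s trials:
#' pink-noise background on every channel plus a 10 Hz alpha component on
#' the parietal channels whose amplitude is `alpha_amp_uv` during the noise
#' phase and rises by the trial's true percent change (plus trial-to-trial
#' jitter) during the speech phase. The amplitude follows raised-cosine
#' ramps starting at speech onset (1.0 s) and offset (4.5 s), so the
#' 0.3-0.8 s baseline and 3.3-4.3 s encoding analysis windows sit in
#' settled regions.
#'
#' @param alpha_true_pct True percent change of alpha amplitude (> -100).
#' @param n_trials Number of trials in the block.
#' @param channels Channel labels to generate (default the full 19-channel
#'   montage); alpha is added to whichever parietal channels are present.
#' @param alpha_amp_uv Baseline alpha amplitude in microvolts.
#' @param noise_sd_uv Pink-noise SD in microvolts.
#' @param trial_jitter_pct SD of the trial-to-trial jitter added to
#'   `alpha_true_pct`.
#' @param ramp_s Raised-cosine ramp duration in s.
#' @param sample_rate_hz Sampling rate (default 1000).
#' @param seed Optional seed.
#' @return An [eeg_recording()] with `n_trials` onsets.
#' @export
synth_eeg_block <- function(alpha_true_pct, n_trials = 1,
                            channels = scalp_channels_1020(),
                            alpha_amp_uv = 12.5, noise_sd_uv = 5,
                            trial_jitter_pct = 0, ramp_s = 0.4,
                            sample_rate_hz = 1000, seed = NULL) {
  if (!(alpha_true_pct > -100))
    stop_invalid("alpha_true_pct must exceed -100")
  fs <- sample_rate_hz
  n_per <- round(6 * fs)
  n <- n_per * n_trials
  with_seed(seed, {
    t_trial <- (seq_len(n_per) - 1) / fs
    profile <- raised_cosine_step(t_trial, 1.0 + ramp_s / 2, ramp_s) -
      raised_cosine_step(t_trial, 4.5 + ramp_s / 2, ramp_s)
    jit <- stats::rnorm(n_trials, 0, trial_jitter_pct)
    gain_per_trial <- pmax(1 + (alpha_true_pct + jit) / 100, 0)
    # amplitude profile of the whole block
    amp <- alpha_amp_uv * (1 + as.vector(outer(profile, gain_per_trial - 1)))
    t_all <- (seq_len(n) - 1) / fs
    samples <- matrix(0, n, length(channels),
                      dimnames = list(NULL, channels))
    for (j in seq_along(channels)) {
      x <- if (noise_sd_uv > 0) pink_noise(n, noise_sd_uv) else numeric(n)
      if (channels[j] %in% parietal_channels()) {
        x <- x + amp * sin(2 * pi * 10 * t_all + stats::runif(1, 0, 2 * pi))
      }
      samples[, j] <- x
    }
    eeg_recording(samples, fs,
                  trial_onsets = seq(1, by = n_per, length.out = n_trials))
  })
}

#' Synthesize a single 6-s EEG trial
#'
#' One-trial convenience wrapper around [synth_eeg_block()] with the full
#' 19-channel montage.
#'
#' @inheritParams synth_eeg_block
#' @param ... Passed to [synth_eeg_block()].
#' @return An [eeg_recording()] with one onset.
#' @export
synth_eeg_trial <- function(alpha_true_pct, ..., seed = NULL) {
  synth_eeg_block(alpha_true_pct, n_trials = 1, ..., seed = seed)
}

#' Synthesize a pupil trace with a known MPD percent change
#'
#' The trace runs from 500 ms before stimulus onset to 6 s after, at
#' 1000 Hz: a base diameter with slow sinusoidal drift, a smooth gamma-
#' shaped dilation starting `onset_s` after stimulus onset and peaking at
#' `peak_s` (inside the 2-6 s analysis window) whose peak is
#' `(mpd_true_pct + jitter)%` of the base diameter, Gaussian sensor noise,
#' and Poisson blinks (100-300 ms) flagged invalid with the diameter forced
#' to zero.
#'
#' @param mpd_true_pct True MPD percent change (> -100).
#' @param base_px Base pupil diameter in pixels.
#' @param sensor_sd_px Sensor noise SD in pixels.
#' @param drift_px Amplitude of the slow (0.05 Hz) drift in pixels.
#' @param blink_rate_hz Expected blinks per second.
#' @param trial_jitter_pct SD of trial-to-trial jitter on the true value.
#' @param onset_s,peak_s Dilation onset and peak times (s after stimulus).
#' @param shape Gamma shape of the dilation curve (larger = sharper peak).
#' @param pre_ms Pre-stimulus span in ms (default 500).
#' @param duration_s Post-onset duration in s (default 6).
#' @param seed Optional seed.
#' @return A [pupil_trace()] with `trial_onset_ms = 0`.
#' @export
synth_pupil_trial <- function(mpd_true_pct, base_px = 1000,
                              sensor_sd_px = 2, drift_px = 3,
                              blink_rate_hz = 0.2, trial_jitter_pct = 0,
                              onset_s = 1.2, peak_s = 3.0, shape = 10,
                              pre_ms = 500, duration_s = 6, seed = NULL) {
  if (!(mpd_true_pct > -100))
    stop_invalid("mpd_true_pct must exceed -100")
  with_seed(seed, {
    time_ms <- seq(-pre_ms, duration_s * 1000 - 1)
    t <- time_ms / 1000
    u <- pmax(t - onset_s, 0) / (peak_s - onset_s)
    bump <- ifelse(u > 0, u^shape * exp(shape * (1 - u)), 0)
    eps <- stats::rnorm(1, 0, trial_jitter_pct)
    d <- base_px +
      drift_px * sin(2 * pi * 0.05 * t + stats::runif(1, 0, 2 * pi)) +
      base_px * (mpd_true_pct + eps) / 100 * bump +
      stats::rnorm(length(t), 0, sensor_sd_px)
    valid <- rep(TRUE, length(t))
    n_blinks <- stats::rpois(1, blink_rate_hz * (pre_ms / 1000 + duration_s))
    if (n_blinks > 0) {
      starts <- stats::runif(n_blinks, min(t), max(t))
      durs <- stats::runif(n_blinks, 0.1, 0.3)
      for (k in seq_len(n_blinks)) {
        valid[t >= starts[k] & t < starts[k] + durs[k]] <- FALSE
      }
    }
    d[!valid] <- 0
    trace <- pupil_trace(time_ms, pmax(d, 1e-6), valid, trial_onset_ms = 0)
    trace
  })
}

#' Generate and analyze a full synthetic cohort end to end
#'
#' For every subject and condition, generates the EEG trial block and the
#' pupil trial series from the subject's latent truth, runs the complete
#' analysis pipelines ([alpha_envelope()] / [trial_alpha_change()] and
#' [deblink_and_interpolate()] / [preprocess_trace()] /
#' [trial_mpd_percent()]), and returns measured next to true values.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer master seed; every subject/condition/modality gets a
#'   derived seed, so results are fully reproducible.
#' @param truth Optional precomputed [draw_cohort_truth()] table.
#' @param verbose Print per-subject progress.
#' @return Data frame with one row per subject x condition: the truth
#'   columns plus `alpha_measured`, `mpd_measured`, `n_pupil_trials`,
#'   `eeg_reliable`.
#' @export
analyze_cohort <- function(spec = default_cohort_spec(), seed = 1,
                           truth = NULL, verbose = FALSE) {
  if (is.null(truth)) truth <- draw_cohort_truth(spec, seed)
  truth$alpha_measured <- NA_real_
  truth$mpd_measured <- NA_real_
  truth$n_pupil_trials <- NA_integer_
  truth$eeg_reliable <- NA
  for (i in seq_len(nrow(truth))) {
    subject <- truth$subject[i]
    condition <- truth$condition[i]
    if (verbose) message("cohort: ", subject, " / ", condition)
    rec <- synth_eeg_block(
      truth$alpha_true[i], n_trials = spec$trials_per_condition,
      channels = spec$eeg$channels,
      alpha_amp_uv = spec$eeg$alpha_amp_uv,
      noise_sd_uv = spec$eeg$noise_sd_uv,
      trial_jitter_pct = spec$eeg$trial_jitter_pct,
      ramp_s = spec$eeg$ramp_s,
      sample_rate_hz = spec$sample_rate_hz,
      seed = derive_seed(seed, subject, condition, "eeg"))
    truth$eeg_reliable[i] <- qc_recording(rec,
      analysis_labels = intersect(parietal_channels(),
                                  colnames(rec$samples)))$reliable
    env <- alpha_envelope(rec)
    trials <- lapply(rec$trial_onsets, function(on)
      trial_alpha_change(env, on,
        analysis_labels = intersect(parietal_channels(),
                                    colnames(env$envelope))))
    truth$alpha_measured[i] <- alpha_condition_summary(trials)$mean_percent_change

    p_seed <- derive_seed(seed, subject, condition, "pupil")
    presults <- lapply(seq_len(spec$trials_per_condition), function(k) {
      trace <- synth_pupil_trial(
        truth$mpd_true[i], base_px = spec$pupil$base_px,
        sensor_sd_px = spec$pupil$sensor_sd_px,
        drift_px = spec$pupil$drift_px,
        blink_rate_hz = spec$pupil$blink_rate_hz,
        trial_jitter_pct = spec$pupil$trial_jitter_pct,
        onset_s = spec$pupil$onset_s, peak_s = spec$pupil$peak_s,
        shape = spec$pupil$shape,
        seed = derive_seed(p_seed, k))
      db <- deblink_and_interpolate(trace)
      if (isTRUE(attr(db, "excluded"))) return(NULL)
      trial_mpd_percent(preprocess_trace(db))
    })
    psum <- pupil_condition_summary(presults, spec$n_warmup_trials)
    truth$mpd_measured[i] <- psum$mean_percent_change
    truth$n_pupil_trials[i] <- psum$n_trials
  }
  truth
}

#' Write a synthetic cohort to disk in the package's exchange formats
#'
#' Per subject and condition: an EEG sample table (CSV) with a JSON event
#' sidecar, and a pupil sample table (CSV); plus the latent truth table.
#' Intended for interface round-trips and small demonstration cohorts;
#' large cohorts are better handled in memory with [analyze_cohort()].
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer master seed.
#' @param out_dir Output directory (created).
#' @param n_pupil_trials Pupil trials written per condition (default all).
#' @return The truth table, invisibly.
#' @export
synth_cohort <- function(spec = default_cohort_spec(), seed = 1, out_dir,
                         n_pupil_trials = spec$trials_per_condition) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- draw_cohort_truth(spec, seed)
  utils::write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  for (i in seq_len(nrow(truth))) {
    subject <- truth$subject[i]
    condition <- truth$condition[i]
    tag <- paste0(subject, "_", gsub("[^0-9A-Za-z]", "", condition))
    rec <- synth_eeg_block(
      truth$alpha_true[i], n_trials = spec$trials_per_condition,
      channels = spec$eeg$channels,
      alpha_amp_uv = spec$eeg$alpha_amp_uv,
      noise_sd_uv = spec$eeg$noise_sd_uv,
      trial_jitter_pct = spec$eeg$trial_jitter_pct,
      ramp_s = spec$eeg$ramp_s, sample_rate_hz = spec$sample_rate_hz,
      seed = derive_seed(seed, subject, condition, "eeg"))
    write_eeg_table(rec, file.path(out_dir, paste0(tag, "_eeg.csv")),
                    events_path = file.path(out_dir, paste0(tag, "_events.json")),
                    condition_label = condition)
    p_seed <- derive_seed(seed, subject, condition, "pupil")
    for (k in seq_len(n_pupil_trials)) {
      trace <- synth_pupil_trial(
        truth$mpd_true[i], base_px = spec$pupil$base_px,
        sensor_sd_px = spec$pupil$sensor_sd_px,
        drift_px = spec$pupil$drift_px,
        blink_rate_hz = spec$pupil$blink_rate_hz,
        trial_jitter_pct = spec$pupil$trial_jitter_pct,
        onset_s = spec$pupil$onset_s, peak_s = spec$pupil$peak_s,
        shape = spec$pupil$shape, seed = derive_seed(p_seed, k))
      write_pupil_table(trace,
                        file.path(out_dir, sprintf("%s_pupil_%03d.csv", tag, k)))
    }
  }
  invisible(truth)
}
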