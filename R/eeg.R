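# EEG alpha-power analysis. The measure of listening effort is the relative
# percent change of the 8-12 Hz Hilbert envelope, averaged over the parietal
# electrodes P3/P4/Pz, between a baseline-in-noise window (0.3-0.8 s after
# noise onset) and the sentence-encoding window (a 1-s window ending 200 ms
# before speech offset, i.e. 3.3-4.3 s into the 6-s trial).

#' The standard 10-20 scalp montage used by the package
#' @return Character vector of 19 channel labels.
#' @export
scalp_channels_1020 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

#' Parietal analysis channels
#' @return `c("P3", "P4", "Pz")`.
#' @export
parietal_channels <- function() c("P3", "P4", "Pz")

#' Construct an EEG recording object
#'
#' @param samples Numeric matrix, samples x channels, amplitudes in microvolts;
#'   column names are the channel labels.
#' @param sample_rate_hz Sampling rate (default 1000 Hz).
#' @param trial_onsets Integer sample indices (1-based) of trial starts; each
#'   6-s trial must fit inside the recording.
#' @param channel_labels Channel labels; defaults to `colnames(samples)`.
#' @param reference_label Reference electrode label (default `"A2"`).
#' @param trial_duration_s Trial length used for the fit check (default 6).
#' @return Object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, sample_rate_hz = 1000,
                          trial_onsets = integer(0),
                          channel_labels = colnames(samples),
                          reference_label = "A2",
                          trial_duration_s = 6) {
  samples <- as.matrix(samples)
  if (is.null(channel_labels) || length(channel_labels) != ncol(samples))
    stop_invalid("channel_labels must name every column of samples")
  colnames(samples) <- channel_labels
  if (!(sample_rate_hz > 0)) stop_invalid("sample rate must be positive")
  trial_onsets <- as.integer(trial_onsets)
  n_trial <- round(trial_duration_s * sample_rate_hz)
  if (length(trial_onsets) &&
      (min(trial_onsets) < 1 ||
       max(trial_onsets) + n_trial - 1 > nrow(samples)))
    stop_invalid("trial windows do not fit inside the recording")
  structure(
    list(samples = samples, sample_rate_hz = sample_rate_hz,
         trial_onsets = trial_onsets, reference_label = reference_label),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channels x %.1f s @ %g Hz, %d trial onsets (ref %s)\n",
              ncol(x$samples), nrow(x$samples) / x$sample_rate_hz,
              x$sample_rate_hz, length(x$trial_onsets), x$reference_label))
  invisible(x)
}

#' Analysis windows for the alpha-power change
#'
#' Defaults: baseline in noise 0.3-0.8 s after trial onset; encoding window
#' 3.3-4.3 s (1 s, ending 200 ms before the 4.5-s speech offset).
#'
#' @param baseline,encoding Two-element numeric `c(start_s, end_s)` relative
#'   to trial onset.
#' @return List with `baseline` and `encoding`.
#' @export
alpha_windows <- function(baseline = c(0.3, 0.8), encoding = c(3.3, 4.3)) {
  stopifnot(length(baseline) == 2, length(encoding) == 2,
            baseline[2] > baseline[1], encoding[2] > encoding[1])
  list(baseline = baseline, encoding = encoding)
}

#' Amplitude-threshold quality control of a recording
#'
#' Fraction of samples whose absolute amplitude reaches `threshold_uv` on
#' each channel; a recording is flagged unreliable when the artifact
#' fraction on any analysis channel reaches `max_fraction`.
#'
#' @param rec An [eeg_recording()].
#' @param threshold_uv Artifact threshold in microvolts (default 80).
#' @param analysis_labels Channels the decision is based on.
#' @param max_fraction Tolerated artifact fraction (default 0.05).
#' @return List with `artifact_fraction` (named, all channels),
#'   `analysis_fraction`, `reliable`, `threshold_uv`.
#' @export
qc_recording <- function(rec, threshold_uv = 80,
                         analysis_labels = parietal_channels(),
                         max_fraction = 0.05) {
  stopifnot(inherits(rec, "eeg_recording"))
  missing <- setdiff(analysis_labels, colnames(rec$samples))
  if (length(missing))
    stop_invalid("missing analysis channel(s): ", paste(missing, collapse = ", "))
  frac <- colMeans(abs(rec$samples) >= threshold_uv)
  analysis_fraction <- max(frac[analysis_labels])
  list(artifact_fraction = frac,
       analysis_fraction = analysis_fraction,
       reliable = analysis_fraction < max_fraction,
       threshold_uv = threshold_uv)
}

#' Alpha-band Hilbert envelope of every channel
#'
#' Pipeline: 50 Hz notch (2nd-order IIR, Q = 30) then 8-12 Hz band-pass
#' (4th-order Butterworth magnitude), both applied zero-phase in the
#' frequency domain, then the Hilbert envelope. Output is aligned
#' sample-for-sample with the input.
#'
#' @param rec An [eeg_recording()] of at least 2 s duration.
#' @param band Alpha band edges in Hz (default `c(8, 12)`).
#' @param order Butterworth order (default 4).
#' @param notch_hz Mains frequency to notch out (default 50; `NULL` disables).
#' @param notch_q Notch quality factor (default 30).
#' @return Object of class `alpha_envelope`: list with `envelope`
#'   (samples x channels matrix), `sample_rate_hz`, `trial_onsets`.
#' @export
alpha_envelope <- function(rec, band = c(8, 12), order = 4,
                           notch_hz = 50, notch_q = 30) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sample_rate_hz
  if (fs < 100)
    stop_invalid("Nyquist violation: sample rate ", fs,
                 " Hz is too low for an ", band[2], " Hz band")
  n <- nrow(rec$samples)
  if (n / fs < 2)
    stop_invalid("recording must be at least 2 s long for stable filtering")
  f <- fft_bin_freqs(n, fs)
  gain <- butter_bandpass_gain(f, band[1], band[2], order)
  if (!is.null(notch_hz)) gain <- gain * notch_gain(f, fs, notch_hz, notch_q)
  env <- apply(rec$samples, 2, envelope_fft, gain = gain)
  dimnames(env) <- dimnames(rec$samples)
  structure(
    list(envelope = env, sample_rate_hz = fs, trial_onsets = rec$trial_onsets),
    class = "alpha_envelope"
  )
}

window_indices <- function(onset, window_s, fs) {
  (onset + floor(window_s[1] * fs)):(onset + ceiling(window_s[2] * fs) - 1)
}

#' Trial-wise alpha-power percent change
#'
#' Averages the alpha envelope over the parietal channels, takes its mean in
#' the baseline and encoding windows, and reports
#' `(encoding - baseline) / baseline * 100`. Positive values are encoding-
#' related alpha increases. A per-electrode map of the same quantity is
#' returned for every channel.
#'
#' @param env An [alpha_envelope()].
#' @param trial_onset 1-based sample index of the trial start.
#' @param windows An [alpha_windows()] list.
#' @param analysis_labels Channels averaged for the headline value.
#' @param power `"amplitude"` (default) uses the envelope magnitude as the
#'   alpha-power measure; `"squared"` uses the squared envelope.
#' @return Object of class `alpha_trial_result`: list with `baseline_mean`,
#'   `encoding_mean`, `percent_change`, `per_electrode_change` (named).
#' @export
trial_alpha_change <- function(env, trial_onset, windows = alpha_windows(),
                               analysis_labels = parietal_channels(),
                               power = c("amplitude", "squared")) {
  stopifnot(inherits(env, "alpha_envelope"))
  power <- match.arg(power)
  fs <- env$sample_rate_hz
  missing <- setdiff(analysis_labels, colnames(env$envelope))
  if (length(missing))
    stop_invalid("missing analysis channel(s): ", paste(missing, collapse = ", "))
  bi <- window_indices(trial_onset, windows$baseline, fs)
  ei <- window_indices(trial_onset, windows$encoding, fs)
  if (min(bi) < 1 || max(ei) > nrow(env$envelope))
    stop_invalid("analysis windows fall outside the recording")
  e <- env$envelope
  if (power == "squared") e <- e^2
  pooled <- rowMeans(e[, analysis_labels, drop = FALSE])
  baseline_mean <- mean(pooled[bi])
  encoding_mean <- mean(pooled[ei])
  if (!(baseline_mean > 0))
    stop_invalid("degenerate baseline: mean alpha power in the baseline window is not positive")
  per_electrode <- (colMeans(e[ei, , drop = FALSE]) -
                      colMeans(e[bi, , drop = FALSE])) /
    colMeans(e[bi, , drop = FALSE]) * 100
  structure(
    list(baseline_mean = baseline_mean, encoding_mean = encoding_mean,
         percent_change = (encoding_mean - baseline_mean) / baseline_mean * 100,
         per_electrode_change = per_electrode),
    class = "alpha_trial_result"
  )
}

#' Subject-by-condition summary of alpha trial results
#'
#' Arithmetic mean of the per-trial percent changes, plus the per-electrode
#' mean map (for topographies).
#'
#' @param trial_results List of [trial_alpha_change()] results (>= 1).
#' @return List with `mean_percent_change`, `n_trials`,
#'   `per_electrode_mean`.
#' @export
alpha_condition_summary <- function(trial_results) {
  if (length(trial_results) == 0)
    stop_invalid("empty input: no trials to summarize")
  pc <- vapply(trial_results, function(r) r$percent_change, numeric(1))
  maps <- vapply(trial_results, function(r) r$per_electrode_change,
                 trial_results[[1]]$per_electrode_change)
  per_electrode <- if (is.matrix(maps)) rowMeans(maps) else maps
  list(mean_percent_change = mean(pc), n_trials = length(pc),
       per_electrode_mean = per_electrode)
}

#' Run the full alpha pipeline over every trial of a recording
#'
#' @param rec An [eeg_recording()] with trial onsets.
#' @param ... Passed to [trial_alpha_change()].
#' @return List of `alpha_trial_result`, one per onset.
#' @export
alpha_trials <- function(rec, ...) {
  env <- alpha_envelope(rec)
  lapply(rec$trial_onsets, function(onset)
    trial_alpha_change(env, onset, ...))
}
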