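# Task-evoked pupillometry. Traces are 1000 Hz right-eye pupil diameters in
# pixels. Preprocessing follows standard practice: blinks are removed with a
# 100-ms pad on each side and bridged by linear interpolation, a 500-ms
# pre-stimulus baseline is subtracted for averaged-curve outputs, and the
# trace is downsampled to 50 Hz by 20-sample bin means. The effort measure
# is the maximum pupil dilation (MPD) in the 2-6 s window as percent change
# over the 0-1 s noise-phase mean, computed on the raw (un-subtracted)
# downsampled trace so that the ratio is scale-invariant.

#' Construct a pupil trace
#'
#' @param time_ms Sample times in ms, strictly increasing at 1-ms spacing.
#' @param diameter_px Pupil diameter in pixels.
#' @param valid Logical per-sample validity flag (FALSE during blinks).
#' @param trial_onset_ms Stimulus onset time in ms (default 0); times before
#'   it are the pre-stimulus span used for the subtractive baseline.
#' @return Object of class `pupil_trace` (a data frame with attributes
#'   `trial_onset_ms` and `excluded`).
#' @export
pupil_trace <- function(time_ms, diameter_px, valid = TRUE,
                        trial_onset_ms = 0) {
  stopifnot(length(time_ms) == length(diameter_px))
  d <- diff(time_ms)
  if (any(d <= 0) || any(abs(d - 1) > 1e-9))
    stop_invalid("time_ms must be strictly increasing at 1 ms spacing")
  valid <- rep_len(as.logical(valid), length(time_ms))
  if (any(diameter_px[valid] <= 0))
    stop_invalid("diameter must be positive where valid")
  structure(
    data.frame(time_ms = time_ms, diameter_px = diameter_px, valid = valid),
    trial_onset_ms = trial_onset_ms, excluded = FALSE,
    class = c("pupil_trace", "data.frame")
  )
}

#' Blink intervals of a trace
#'
#' Runs of at least `min_run` consecutive invalid samples are treated as
#' blinks.
#'
#' @param trace A [pupil_trace()].
#' @param min_run Minimum invalid-run length in samples (default 3).
#' @return Data frame with `start_ms` and `end_ms` (inclusive), one row per
#'   blink.
#' @export
detect_blinks <- function(trace, min_run = 3) {
  inv <- !trace$valid
  if (!any(inv))
    return(data.frame(start_ms = numeric(0), end_ms = numeric(0)))
  r <- rle(inv)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_run
  data.frame(start_ms = trace$time_ms[starts[keep]],
             end_ms = trace$time_ms[ends[keep]])
}

#' Deblink a pupil trace and bridge the gaps by linear interpolation
#'
#' Each blink is widened by `pad_ms` on both sides; samples inside the
#' padded interval are replaced by the straight line between the nearest
#' surviving samples. A gap touching the trace edge has no anchor on that
#' side and cannot be interpolated: the trial is flagged excluded and
#' returned unchanged.
#'
#' @param trace A [pupil_trace()].
#' @param pad_ms Pad on each side of a blink in ms (default 100).
#' @param min_run Passed to [detect_blinks()].
#' @return A `pupil_trace` with no invalid samples (on recoverable trials),
#'   or the input with attribute `excluded = TRUE`.
#' @export
deblink_and_interpolate <- function(trace, pad_ms = 100, min_run = 3) {
  stopifnot(inherits(trace, "pupil_trace"))
  blinks <- detect_blinks(trace, min_run)
  short_invalid <- !trace$valid
  if (nrow(blinks) == 0 && !any(short_invalid)) return(trace)
  n <- nrow(trace)
  drop <- short_invalid  # isolated invalid samples are interpolated too
  for (i in seq_len(nrow(blinks))) {
    drop <- drop | (trace$time_ms >= blinks$start_ms[i] - pad_ms &
                      trace$time_ms <= blinks$end_ms[i] + pad_ms)
  }
  if (drop[1] || drop[n]) {
    attr(trace, "excluded") <- TRUE
    return(trace)
  }
  keep_idx <- which(!drop)
  out <- trace
  out$diameter_px[drop] <- stats::approx(trace$time_ms[keep_idx],
                                         trace$diameter_px[keep_idx],
                                         xout = trace$time_ms[drop])$y
  out$valid <- TRUE
  out
}

#' Baseline-correct and downsample a deblinked trace to 50 Hz
#'
#' The subtractive baseline is the mean diameter over the `baseline_ms`
#' window before stimulus onset (default -500 to 0 ms). Downsampling takes
#' means over consecutive non-overlapping bins of `bin` samples (20 at
#' 1000 Hz -> 50 Hz); because the mean is linear this commutes exactly with
#' the baseline subtraction. Both the raw and the baseline-subtracted
#' downsampled series are returned: ratio metrics (MPD percent change) use
#' the raw series, averaged-curve outputs use the corrected one.
#'
#' @param trace A deblinked [pupil_trace()].
#' @param baseline_ms Two-element window relative to onset (default
#'   `c(-500, 0)`).
#' @param bin Samples per output bin (default 20).
#' @return Object of class `pupil_trace_50`: data frame with `time_ms`
#'   (bin centers), `diameter_px` (raw), `diameter_corrected`;
#'   attributes `baseline_pre_px`, `trial_onset_ms`, `excluded`.
#' @export
preprocess_trace <- function(trace, baseline_ms = c(-500, 0), bin = 20) {
  stopifnot(inherits(trace, "pupil_trace"))
  onset <- attr(trace, "trial_onset_ms")
  if (isTRUE(attr(trace, "excluded")) || any(!trace$valid))
    stop_invalid("trace must be deblinked (and recoverable) before preprocessing")
  rel <- trace$time_ms - onset
  pre <- rel >= baseline_ms[1] & rel < baseline_ms[2]
  if (sum(pre) < (baseline_ms[2] - baseline_ms[1]))
    stop_invalid("missing pre-stimulus span: need samples covering ",
                 baseline_ms[1], " to ", baseline_ms[2], " ms")
  baseline <- mean(trace$diameter_px[pre])
  n_bins <- floor(nrow(trace) / bin)
  take <- seq_len(n_bins * bin)
  raw <- colMeans(matrix(trace$diameter_px[take], nrow = bin))
  tt <- colMeans(matrix(trace$time_ms[take], nrow = bin))
  structure(
    data.frame(time_ms = tt, diameter_px = raw,
               diameter_corrected = raw - baseline),
    baseline_pre_px = baseline, trial_onset_ms = onset,
    excluded = FALSE,
    class = c("pupil_trace_50", "data.frame")
  )
}

#' Maximum-pupil-dilation percent change of one trial
#'
#' On the raw downsampled trace: mean diameter over the noise phase
#' (0-1 s after onset) is the divisive baseline; the maximum diameter over
#' the encoding window (2-6 s) is the MPD; the result is
#' `(mpd - noise_mean) / noise_mean * 100`.
#'
#' @param pp A [preprocess_trace()] result.
#' @param noise_window_s Noise-phase window in s relative to onset.
#' @param encoding_window_s Encoding window in s relative to onset.
#' @return Object of class `pupil_trial_result`: list with `noise_mean_px`,
#'   `mpd_px`, `percent_change`, `baseline_pre_px`, `excluded`.
#' @export
trial_mpd_percent <- function(pp, noise_window_s = c(0, 1),
                              encoding_window_s = c(2, 6)) {
  stopifnot(inherits(pp, "pupil_trace_50"))
  rel <- (pp$time_ms - attr(pp, "trial_onset_ms")) / 1000
  ni <- rel >= noise_window_s[1] & rel < noise_window_s[2]
  ei <- rel >= encoding_window_s[1] & rel < encoding_window_s[2]
  if (!any(ni) || !any(ei))
    stop_invalid("analysis windows fall outside the trace")
  noise_mean <- mean(pp$diameter_px[ni])
  if (!(noise_mean > 0))
    stop_invalid("degenerate baseline: noise-phase mean diameter is not positive")
  mpd <- max(pp$diameter_px[ei])
  structure(
    list(noise_mean_px = noise_mean, mpd_px = mpd,
         percent_change = (mpd - noise_mean) / noise_mean * 100,
         baseline_pre_px = attr(pp, "baseline_pre_px"),
         excluded = FALSE),
    class = "pupil_trial_result"
  )
}

#' Subject-by-condition summary of pupil trial results
#'
#' Drops the first `n_exclude_first` trials in presentation order (warm-up:
#' habituation/arousal) and any excluded trials, then averages the percent
#' changes.
#'
#' @param trial_results List of [trial_mpd_percent()] results (or entries
#'   `NULL`/flagged excluded for unrecoverable trials), in presentation
#'   order.
#' @param n_exclude_first Number of leading trials to drop (default 5).
#' @return List with `mean_percent_change`, `n_trials`.
#' @export
pupil_condition_summary <- function(trial_results, n_exclude_first = 5) {
  if (length(trial_results) <= n_exclude_first)
    stop_invalid("empty input: need more than ", n_exclude_first, " trials")
  kept <- trial_results[-seq_len(n_exclude_first)]
  pc <- unlist(lapply(kept, function(r) {
    if (is.null(r) || isTRUE(r$excluded)) NULL else r$percent_change
  }))
  if (length(pc) == 0)
    stop_invalid("empty input: all trials were excluded")
  list(mean_percent_change = mean(pc), n_trials = length(pc))
}
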