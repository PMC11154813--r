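# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

# Flat pupil trace with an optional plateaued peak, exact by construction.
make_peak_trace <- function(base_px = 1000, peak_px = base_px,
                            peak_at_s = 3, plateau_s = 0.1,
                            pre_ms = 500, duration_s = 6) {
  time_ms <- seq(-pre_ms, duration_s * 1000 - 1)
  t <- time_ms / 1000
  d <- rep(base_px, length(t))
  if (peak_px != base_px) {
    ramp <- 0.25
    up <- t >= peak_at_s - ramp & t < peak_at_s
    d[up] <- base_px + (peak_px - base_px) * (t[up] - (peak_at_s - ramp)) / ramp
    top <- t >= peak_at_s & t < peak_at_s + plateau_s
    d[top] <- peak_px
    down <- t >= peak_at_s + plateau_s & t < peak_at_s + plateau_s + ramp
    d[down] <- peak_px - (peak_px - base_px) *
      (t[down] - (peak_at_s + plateau_s)) / ramp
  }
  pupil_trace(time_ms, d, TRUE, trial_onset_ms = 0)
}

# Linear-ramp pupil trace (for interpolation exactness checks).
make_ramp_trace <- function(from_px = 1000, to_px = 1100,
                            pre_ms = 0, duration_s = 6) {
  time_ms <- seq(-pre_ms, duration_s * 1000 - 1)
  d <- from_px + (to_px - from_px) *
    (time_ms - time_ms[1]) / (time_ms[length(time_ms)] - time_ms[1])
  pupil_trace(time_ms, d, TRUE, trial_onset_ms = 0)
}

# Mark an interval of a trace invalid (a synthetic blink).
add_blink <- function(trace, start_ms, end_ms) {
  hit <- trace$time_ms >= start_ms & trace$time_ms <= end_ms
  trace$valid[hit] <- FALSE
  trace
}

# Reduced cohort for fast end-to-end interface tests.
tiny_cohort_spec <- function(n = 3, trials = 8) {
  cohort_spec(n_tinnitus = n, n_control = n, trials_per_condition = trials,
              n_warmup_trials = 2)
}
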