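make_recording <- function(signal_fun, channels = parietal_channels(),
                           fs = 1000, duration = 6, onsets = 1L) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  samples <- vapply(channels, function(ch) signal_fun(t), numeric(length(t)))
  eeg_recording(samples, fs, trial_onsets = onsets)
}

test_that("amplitude QC counts artifact samples and flags unreliable channels", {
  rec <- make_recording(function(t) rep(10, length(t)))
  qc <- qc_recording(rec)
  expect_equal(unname(qc$artifact_fraction["P3"]), 0)
  expect_true(qc$reliable)

  rec2 <- make_recording(function(t)
    ifelse(seq_along(t) %% 2 == 0, 100, 10))
  qc2 <- qc_recording(rec2)
  expect_equal(unname(qc2$artifact_fraction["Pz"]), 0.5)
  expect_false(qc2$reliable)

  qc3 <- effortlab:::with_seed(12, {
    r <- make_recording(function(t) stats::rnorm(length(t), 0, 30),
                        duration = 60)
    qc_recording(r)
  })
  expect_lt(abs(unname(qc3$artifact_fraction["P3"]) -
                  2 * (1 - pnorm(80 / 30))), 0.0015)

  rec4 <- make_recording(function(t) t, channels = c("P3", "P4"))
  expect_error(qc_recording(rec4), "Pz")
})

test_that("alpha envelope passes in-band amplitude and rejects 50 Hz and 2 Hz", {
  env_of <- function(freq, amp) {
    rec <- make_recording(function(t) amp * sin(2 * pi * freq * t))
    e <- alpha_envelope(rec)$envelope[, "P3"]
    mean(e[1000:5000])
  }
  expect_equal(env_of(10, 20), 20, tolerance = 0.02 * 20)
  expect_lt(env_of(50, 50), 1)
  expect_lt(env_of(2, 50), 2.5)

  low_fs <- eeg_recording(matrix(0, 500, 3,
                                 dimnames = list(NULL, parietal_channels())),
                          sample_rate_hz = 50)
  expect_error(alpha_envelope(low_fs), "Nyquist")
  short <- eeg_recording(matrix(0, 500, 3,
                                dimnames = list(NULL, parietal_channels())),
                         sample_rate_hz = 1000)
  expect_error(alpha_envelope(short), "2 s")
})

test_that("trial percent change matches the injected amplitude ratio", {
  # identical baseline and encoding amplitude -> 0%
  rec0 <- synth_eeg_trial(0, noise_sd_uv = 0.01, trial_jitter_pct = 0,
                          channels = parietal_channels(), seed = 1)
  expect_equal(trial_alpha_change(alpha_envelope(rec0), 1)$percent_change, 0,
               tolerance = 0.5)

  # halving the amplitude gives -50%
  rec_half <- synth_eeg_trial(-50, noise_sd_uv = 0.01, trial_jitter_pct = 0,
                              channels = parietal_channels(), seed = 2)
  expect_equal(trial_alpha_change(alpha_envelope(rec_half), 1)$percent_change,
               -50, tolerance = 1)

  # injected-modulation recovery for ratios 1.5, 2, 3
  for (r in c(1.5, 2, 3)) {
    rec <- synth_eeg_trial(100 * (r - 1), noise_sd_uv = 0.01,
                           trial_jitter_pct = 0,
                           channels = parietal_channels(),
                           seed = derive_seed(5, r))
    got <- trial_alpha_change(alpha_envelope(rec), 1)$percent_change
    expect_equal(got, 100 * (r - 1), tolerance = 3)
  }

  # degenerate (zero-power) baseline is an error, not NaN
  zero <- eeg_recording(matrix(0, 6000, 3,
                               dimnames = list(NULL, parietal_channels())),
                        trial_onsets = 1L)
  expect_error(trial_alpha_change(alpha_envelope(zero), 1), "degenerate")
})

test_that("percent change is invariant to recording scale", {
  rec <- synth_eeg_trial(120, noise_sd_uv = 2, trial_jitter_pct = 0,
                         seed = 42)
  pc1 <- trial_alpha_change(alpha_envelope(rec), 1)$percent_change
  rec$samples <- rec$samples * 3.7
  pc2 <- trial_alpha_change(alpha_envelope(rec), 1)$percent_change
  expect_equal(pc1, pc2, tolerance = 1e-9)
  expect_length(trial_alpha_change(alpha_envelope(rec), 1)$per_electrode_change,
                ncol(rec$samples))
})

test_that("analysis windows track the trial onset sample-for-sample", {
  fs <- 1000
  w <- alpha_windows()
  idx1 <- effortlab:::window_indices(1L, w$baseline, fs)
  idx2 <- effortlab:::window_indices(101L, w$baseline, fs)
  expect_identical(idx2, idx1 + 100L)
  expect_length(effortlab:::window_indices(1L, w$encoding, fs), 1000)
  expect_equal(idx1[1], 301)
})

test_that("Hilbert envelope agrees with a rectify-and-smooth oracle on narrowband signals", {
  skip_if_not_installed("signal")
  fs <- 1000
  t <- seq(0, 6 - 1 / fs, by = 1 / fs)
  x <- (10 + 4 * sin(2 * pi * 1.5 * t)) * sin(2 * pi * 10 * t)
  env <- hilbert_envelope(x)
  # cutoff between the 1.5 Hz modulation and the rectified carrier's first
  # harmonic at 20 Hz
  lp <- signal::butter(4, 6 / (fs / 2), "low")
  oracle <- signal::filtfilt(lp, abs(x)) * pi / 2  # rectified-sine mean factor
  central <- seq(round(0.1 * length(t)), round(0.9 * length(t)))
  rel_rms <- sqrt(mean((env[central] - oracle[central])^2)) /
    sqrt(mean(oracle[central]^2))
  expect_lt(rel_rms, 0.05)
})

test_that("condition summaries average trials and per-electrode maps", {
  fake <- function(pc) structure(list(percent_change = pc,
                                      per_electrode_change = c(P3 = pc, P4 = pc)),
                                 class = "alpha_trial_result")
  s <- alpha_condition_summary(list(fake(100), fake(200)))
  expect_equal(s$mean_percent_change, 150)
  expect_equal(unname(s$per_electrode_mean["P3"]), 150)
  expect_equal(alpha_condition_summary(list(fake(42)))$mean_percent_change, 42)
  expect_error(alpha_condition_summary(list()), "empty")
})
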