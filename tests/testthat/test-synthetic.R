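test_that("cohort spec validates and merges overrides", {
  spec <- default_cohort_spec()
  expect_s3_class(spec, "cohort_spec")
  expect_equal(spec$n_tinnitus, 21)
  expect_equal(spec$n_control, 26)
  expect_equal(spec$trials_per_condition, 90)
  expect_length(spec$conditions, 4)

  small <- cohort_spec(n_tinnitus = 3, eeg = list(noise_sd_uv = 1))
  expect_equal(small$n_tinnitus, 3)
  expect_equal(small$eeg$noise_sd_uv, 1)
  expect_equal(small$eeg$alpha_amp_uv, spec$eeg$alpha_amp_uv)

  expect_error(cohort_spec(n_control = 1), "at least 2")
  expect_error(cohort_spec(trials_per_condition = 4), "exceed")
})

test_that("cohort truth is deterministic and zero-SD specs hit group means", {
  spec <- tiny_cohort_spec()
  t1 <- draw_cohort_truth(spec, seed = 99)
  t2 <- draw_cohort_truth(spec, seed = 99)
  expect_identical(t1, t2)
  t3 <- draw_cohort_truth(spec, seed = 100)
  expect_false(identical(t1$alpha_true, t3$alpha_true))

  expect_true(all(t1$srt80 >= t1$srt50))
  expect_true(all(is.na(t1$thi[t1$group == "control"])))
  expect_true(all(!is.na(t1$thi[t1$group == "tinnitus"])))

  ac <- default_cohort_spec()$alpha_change
  mp <- default_cohort_spec()$mpd
  ac[c("tinnitus_sd", "control_sd")] <- 0
  mp[c("tinnitus_sd", "control_sd")] <- 0
  frozen <- cohort_spec(n_tinnitus = 3, n_control = 3,
                        alpha_change = ac, mpd = mp)
  tf <- draw_cohort_truth(frozen, seed = 1)
  for (ci in seq_len(4)) {
    rows <- tf$condition == frozen$conditions[ci] & tf$group == "control"
    expect_true(all(tf$alpha_true[rows] == ac$control_mean[ci]))
    expect_true(all(tf$mpd_true[rows] == mp$control_mean[ci]))
  }
})

test_that("synthetic EEG trials recover the injected alpha change", {
  # zero effect, default noise: recovery within the noise floor
  rec0 <- synth_eeg_trial(0, trial_jitter_pct = 0,
                          channels = parietal_channels(), seed = 3)
  pc0 <- trial_alpha_change(alpha_envelope(rec0), 1)$percent_change
  expect_lt(abs(pc0), 3)

  # doubling the alpha amplitude scale leaves the ratio unchanged
  r1 <- synth_eeg_trial(150, alpha_amp_uv = 12.5, noise_sd_uv = 0,
                        trial_jitter_pct = 0,
                        channels = parietal_channels(), seed = 4)
  r2 <- synth_eeg_trial(150, alpha_amp_uv = 25, noise_sd_uv = 0,
                        trial_jitter_pct = 0,
                        channels = parietal_channels(), seed = 4)
  pc1 <- trial_alpha_change(alpha_envelope(r1), 1)$percent_change
  pc2 <- trial_alpha_change(alpha_envelope(r2), 1)$percent_change
  expect_equal(pc1, pc2, tolerance = 0.1)
  expect_equal(pc1, 150, tolerance = 3)

  expect_error(synth_eeg_trial(-120), "-100")
})

test_that("many-trial EEG blocks average out the trial jitter", {
  n_trials <- 30
  rec <- synth_eeg_block(183.6, n_trials = n_trials,
                         channels = parietal_channels(),
                         trial_jitter_pct = 30, seed = 11)
  env <- alpha_envelope(rec)
  trials <- lapply(rec$trial_onsets, function(on)
    trial_alpha_change(env, on))
  m <- alpha_condition_summary(trials)$mean_percent_change
  # jitter SE = 30 / sqrt(30); allow 3 SE plus a 2-point pipeline tolerance
  expect_lt(abs(m - 183.6), 3 * 30 / sqrt(n_trials) + 2)
})

test_that("synthetic pupil trials recover the injected MPD", {
  # noise-free: exact recovery up to window discretization
  tr <- synth_pupil_trial(10.7, sensor_sd_px = 0, drift_px = 0,
                          blink_rate_hz = 0, seed = 1)
  pc <- trial_mpd_percent(preprocess_trace(tr))$percent_change
  expect_equal(pc, 10.7, tolerance = 0.15)

  tr0 <- synth_pupil_trial(0, sensor_sd_px = 0, drift_px = 0,
                           blink_rate_hz = 0, seed = 1)
  expect_equal(trial_mpd_percent(preprocess_trace(tr0))$percent_change, 0,
               tolerance = 0.05)

  # subject mean over many default trials lands near the truth
  run_subject <- function(blink_rate) {
    res <- lapply(1:40, function(k) {
      trace <- synth_pupil_trial(10.7, blink_rate_hz = blink_rate,
                                 trial_jitter_pct = 1.5,
                                 seed = derive_seed(77, blink_rate, k))
      db <- deblink_and_interpolate(trace)
      if (isTRUE(attr(db, "excluded"))) return(NULL)
      trial_mpd_percent(preprocess_trace(db))
    })
    pupil_condition_summary(res)$mean_percent_change
  }
  m_blinks <- run_subject(0.2)
  m_clean <- run_subject(0)
  expect_lt(abs(m_clean - 10.7), 3 * 1.5 / sqrt(35) + 0.15)
  # interpolation robustness: blinks move the subject mean only slightly
  expect_lt(abs(m_blinks - m_clean), 0.3)
})

test_that("analyze_cohort returns measured values tracking the truth", {
  spec <- tiny_cohort_spec(n = 2, trials = 8)
  res <- analyze_cohort(spec, seed = 5)
  expect_equal(nrow(res), 2 * 2 * 4)
  expect_true(all(is.finite(res$alpha_measured)))
  expect_true(all(is.finite(res$mpd_measured)))
  expect_true(all(res$n_pupil_trials <= spec$trials_per_condition -
                    spec$n_warmup_trials))
  # per-subject recovery: jitter SE per subject at 6 used trials
  se_alpha <- spec$eeg$trial_jitter_pct / sqrt(8)
  expect_lt(max(abs(res$alpha_measured - res$alpha_true)), 4 * se_alpha + 3)
  se_mpd <- spec$pupil$trial_jitter_pct / sqrt(6)
  expect_lt(max(abs(res$mpd_measured - res$mpd_true)), 4 * se_mpd + 0.3)
  # determinism of the full chain
  res2 <- analyze_cohort(spec, seed = 5)
  expect_identical(res, res2)
})

test_that("derived seeds are stable and distinct across labels", {
  expect_identical(derive_seed(1, "a", 2), derive_seed(1, "a", 2))
  expect_false(derive_seed(1, "a") == derive_seed(1, "b"))
  expect_false(derive_seed(1, "a") == derive_seed(2, "a"))
  s <- vapply(1:1000, function(i) derive_seed(7, "x", i), numeric(1))
  expect_equal(length(unique(s)), 1000)
  expect_true(all(s >= 1 & s <= 2^31 - 2))
})
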