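test_that("THI scoring sums 4/2/0 over exactly 25 items", {
  expect_equal(thi_score(rep("no", 25)), 0L)
  expect_equal(thi_score(rep("yes", 25)), 100L)
  expect_equal(thi_score(c(rep("yes", 10), rep("sometimes", 6),
                           rep("no", 9))), 52L)
  expect_equal(thi_score(rep("Yes", 25)), 100L)  # case-insensitive
  expect_error(thi_score(rep("yes", 24)), "25 items")
  expect_error(thi_score(c(rep("yes", 24), "maybe")), "maybe")
})

test_that("reference THI score set has the expected sample SD", {
  thi <- default_cohort_spec()$thi_scores
  expect_length(thi, 21)
  expect_equal(round(sd(thi), 1), 9.9)
})

test_that("Cohen's d matches the pooled-SD formula and hand values", {
  expect_equal(cohens_d(c(1, 2, 3), c(4, 5, 6)), -3)
  expect_equal(cohens_d_summary(10, 2, 10, 8, 2, 10), 1)
  # summary and sample paths agree
  a <- c(2.3, 4.1, 3.3, 5.0)
  b <- c(1.1, 2.2, 0.9)
  expect_equal(cohens_d(a, b),
               cohens_d_summary(mean(a), sd(a), length(a),
                                mean(b), sd(b), length(b)))
  # the reference alpha-change cell summaries give a large effect
  spec <- default_cohort_spec()$alpha_change
  d <- cohens_d_summary(spec$tinnitus_mean[1], spec$tinnitus_sd[1], 21,
                        spec$control_mean[1], spec$control_sd[1], 26)
  expect_gt(abs(d), 0.9)
  expect_lt(abs(d), 1.0)
})

test_that("group comparison reproduces hand-computed t tests", {
  cmp <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(cmp$method, "pooled")
  expect_equal(cmp$t, -3.674, tolerance = 1e-3)
  expect_equal(cmp$df, 4)
  expect_equal(cmp$cohens_d, -3)

  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p.value, 1)
  expect_equal(same$cohens_d, 0)

  expect_error(compare_groups(1, c(1, 2)), "at least 2")
  expect_error(compare_groups(c(1, NA), c(1, 2)), "non-finite")
})

test_that("Levene's test gates pooled versus Welch", {
  # grossly unequal variances -> Levene significant -> Welch
  a <- effortlab:::with_seed(4, rnorm(40, 0, 1))
  b <- effortlab:::with_seed(5, rnorm(40, 0, 12))
  cmp <- compare_groups(a, b)
  expect_lt(cmp$levene_p, 0.05)
  expect_equal(cmp$method, "welch")
  expect_lt(cmp$df, 78)

  # equal variances -> pooled, df = n1 + n2 - 2
  b2 <- effortlab:::with_seed(6, rnorm(40, 0.5, 1))
  cmp2 <- compare_groups(a, b2)
  expect_gte(cmp2$levene_p, 0.05)
  expect_equal(cmp2$method, "pooled")
  expect_equal(cmp2$df, 78)

  # Levene internals agree with the explicit absolute-deviation ANOVA
  vals <- c(a, b)
  grp <- rep(c("a", "b"), each = 40)
  z <- abs(vals - ave(vals, grp))
  ref <- anova(lm(z ~ grp))
  lev <- effortlab:::levene_test(vals, grp)
  expect_equal(lev$statistic, ref$`F value`[1])
  expect_equal(lev$p.value, ref$`Pr(>F)`[1])
})

test_that("Welch and pooled t agree for equal variances and sizes", {
  a <- effortlab:::with_seed(7, rnorm(30, 0, 2))
  b <- effortlab:::with_seed(8, rnorm(30, 1, 2))
  # pooled t equals Welch t exactly when n1 = n2 (identical standard error)
  tp <- t.test(a, b, var.equal = TRUE)
  tw <- t.test(a, b, var.equal = FALSE)
  expect_equal(unname(tp$statistic), unname(tw$statistic), tolerance = 1e-12)
  cmp <- compare_groups(a, b)
  expect_equal(cmp$t, unname(tp$statistic), tolerance = 1e-12)
})

test_that("Pearson correlation reproduces hand values and errors cleanly", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  got <- pearson_correlation(x, c(2, 1, 4, 3))
  expect_equal(got$r, 0.6, tolerance = 1e-12)
  expect_equal(got$n, 4)
  ref <- cor.test(x, c(2, 1, 4, 3))
  expect_equal(got$p.value, ref$p.value)
  expect_error(pearson_correlation(x, c(1, 1, 1, 1)), "zero variance")
  expect_error(pearson_correlation(1:2, 1:2), ">= 3")
})

test_that("noncentral-t power matches power.t.test", {
  for (n in c(10, 17, 40)) {
    for (d in c(0.5, 1.16)) {
      # power.t.test's two-sided power keeps only the upper rejection
      # region; subtract the lower-tail mass before comparing
      df <- 2 * n - 2
      tc <- qt(1 - 0.05 / 2, df)
      lower_tail <- pt(-tc, df, d * sqrt(n / 2))
      expect_equal(
        t_test_power(n, d, 0.05, "two") - lower_tail,
        power.t.test(n = n, delta = d, sd = 1, sig.level = 0.05,
                     type = "two.sample")$power,
        tolerance = 1e-6)
      expect_equal(
        t_test_power(n, d, 0.05, "one"),
        power.t.test(n = n, delta = d, sd = 1, sig.level = 0.05,
                     type = "two.sample",
                     alternative = "one.sided")$power,
        tolerance = 1e-6)
    }
  }
})

test_that("required sample size inverts the power function", {
  n_one <- required_sample_size(1.16, 0.05, 0.95, "one")
  expect_equal(n_one, 17)
  expect_gte(t_test_power(n_one, 1.16, 0.05, "one"), 0.95)
  expect_lt(t_test_power(n_one - 1, 1.16, 0.05, "one"), 0.95)

  n_two <- required_sample_size(1.16, 0.05, 0.95, "two")
  expect_gt(n_two, n_one)
  expect_gt(required_sample_size(0.8, 0.05, 0.95, "one"), n_one)
  expect_error(required_sample_size(-1), "positive")
  expect_error(required_sample_size(0.01, n_max = 50), "iteration cap")
})

test_that("reference-parameter cohorts separate groups almost surely", {
  # MPD cell with a huge standardized difference: rejection is a sampling
  # near-certainty, so check the rate over seeded replicates
  spec <- default_cohort_spec()$mpd
  reject <- effortlab:::with_seed(1234, vapply(seq_len(500), function(i) {
    tin <- rnorm(21, spec$tinnitus_mean[1], spec$tinnitus_sd[1])
    ctl <- rnorm(26, spec$control_mean[1], spec$control_sd[1])
    compare_groups(tin, ctl)$p.value < 0.05
  }, logical(1)))
  expect_gte(mean(reject), 0.99)
})
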