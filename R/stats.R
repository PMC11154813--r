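# Group statistics: THI questionnaire scoring, Levene-gated independent
# t tests with Cohen's d, Pearson correlation, and a noncentral-t power
# analysis for the two-sample design.

#' Score a 25-item Tinnitus Handicap Inventory response set
#'
#' Items are answered yes / sometimes / no, scored 4 / 2 / 0; the total is
#' their sum (range 0-100).
#'
#' @param responses Character vector of exactly 25 answers among
#'   `"yes"`, `"sometimes"`, `"no"` (case-insensitive).
#' @return Integer total score.
#' @export
thi_score <- function(responses) {
  responses <- tolower(as.character(responses))
  if (length(responses) != 25)
    stop_invalid("invalid input: THI needs exactly 25 items, got ",
                 length(responses))
  bad <- setdiff(unique(responses), c("yes", "sometimes", "no"))
  if (length(bad))
    stop_invalid("invalid input: unknown answer(s): ", paste(bad, collapse = ", "))
  as.integer(4 * sum(responses == "yes") + 2 * sum(responses == "sometimes"))
}

# Classic (mean-centered) Levene test for two or more groups.
levene_test <- function(values, groups) {
  groups <- factor(groups)
  z <- abs(values - stats::ave(values, groups))
  # near-zero within-group spread of z makes the F test degenerate; the
  # statistic is still the right summary, so silence lm's perfect-fit warning
  fit <- suppressWarnings(stats::anova(stats::lm(z ~ groups)))
  list(statistic = fit$`F value`[1], p.value = fit$`Pr(>F)`[1])
}

#' Pooled-SD Cohen's d from group summaries
#'
#' @param mean1,sd1,n1 First group's mean, SD and size.
#' @param mean2,sd2,n2 Second group's mean, SD and size.
#' @return Standardized mean difference `(mean1 - mean2) / sd_pooled`.
#' @export
cohens_d_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  (mean1 - mean2) / sp
}

#' Pooled-SD Cohen's d from two samples
#'
#' @param a,b Numeric vectors.
#' @return Standardized mean difference.
#' @export
cohens_d <- function(a, b) {
  cohens_d_summary(mean(a), stats::sd(a), length(a),
                   mean(b), stats::sd(b), length(b))
}

#' Compare two groups with a Levene-gated independent t test
#'
#' Levene's test (mean-centered) checks variance homogeneity first; if its
#' p-value is at least `alpha_levene` a pooled-variance Student t test is
#' used, otherwise Welch's. The two-sided p-value, pooled-SD Cohen's d and
#' the group summaries are reported.
#'
#' @param a,b Numeric vectors with at least two values each.
#' @param alpha_levene Threshold for switching to Welch (default 0.05).
#' @return Object of class `group_comparison`: list with group summaries
#'   (`n`, `mean`, `sd`), `levene_statistic`, `levene_p`, `method`
#'   (`"pooled"` or `"welch"`), `t`, `df`, `p.value`, `cohens_d`.
#' @export
compare_groups <- function(a, b, alpha_levene = 0.05) {
  if (length(a) < 2 || length(b) < 2)
    stop_invalid("invalid input: each group needs at least 2 values")
  if (!all(is.finite(c(a, b))))
    stop_invalid("invalid input: non-finite values")
  lev <- levene_test(c(a, b), rep(c("a", "b"), c(length(a), length(b))))
  pooled <- is.na(lev$p.value) || lev$p.value >= alpha_levene
  tt <- stats::t.test(a, b, var.equal = pooled)
  structure(
    list(n = c(length(a), length(b)),
         mean = c(mean(a), mean(b)),
         sd = c(stats::sd(a), stats::sd(b)),
         levene_statistic = lev$statistic, levene_p = lev$p.value,
         method = if (pooled) "pooled" else "welch",
         t = unname(tt$statistic), df = unname(tt$parameter),
         p.value = tt$p.value,
         cohens_d = cohens_d(a, b)),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group 1: %.3f +/- %.3f (n=%d); group 2: %.3f +/- %.3f (n=%d)\n",
              x$mean[1], x$sd[1], x$n[1], x$mean[2], x$sd[2], x$n[2]))
  cat(sprintf("Levene p = %.3g -> %s t test: t(%.1f) = %.3f, p = %.3g, d = %.2f\n",
              x$levene_p, x$method, x$df, x$t, x$p.value, x$cohens_d))
  invisible(x)
}

#' Pearson correlation with a t-based two-sided p-value
#'
#' @param x,y Numeric vectors of equal length >= 3, each with nonzero
#'   variance.
#' @return List with `r`, `p.value`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop_invalid("invalid input: need equal lengths >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_invalid("undefined correlation: an input has zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p.value = ct$p.value, n = length(x))
}

#' Power of a two-sample t test via the noncentral t distribution
#'
#' For per-group size `n` and effect size `d`, the test statistic under the
#' alternative is noncentral t with `df = 2n - 2` and noncentrality
#' `d * sqrt(n/2)`.
#'
#' @param n Per-group sample size (>= 2).
#' @param d Cohen's d (> 0).
#' @param alpha Type-I error level.
#' @param tails `"one"` or `"two"`.
#' @return Power (probability of rejecting).
#' @export
t_test_power <- function(n, d, alpha = 0.05, tails = c("one", "two")) {
  tails <- match.arg(tails)
  stopifnot(n >= 2, d > 0, alpha > 0, alpha < 1)
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  if (tails == "one") {
    1 - stats::pt(stats::qt(1 - alpha, df), df, ncp)
  } else {
    tc <- stats::qt(1 - alpha / 2, df)
    1 - stats::pt(tc, df, ncp) + stats::pt(-tc, df, ncp)
  }
}

#' Smallest per-group sample size reaching a target power
#'
#' Iterates `n` upward from 2 until [t_test_power()] reaches `power`.
#'
#' @param d Cohen's d (> 0).
#' @param alpha Type-I error level (default 0.05).
#' @param power Target power (default 0.95).
#' @param tails `"one"` or `"two"`.
#' @param n_max Iteration cap.
#' @return Smallest per-group `n` with power >= `power`.
#' @export
required_sample_size <- function(d, alpha = 0.05, power = 0.95,
                                 tails = c("one", "two"), n_max = 1e5) {
  tails <- match.arg(tails)
  if (!(d > 0)) stop_invalid("effect size d must be positive")
  if (!(power > 0 && power < 1)) stop_invalid("power must be in (0, 1)")
  for (n in 2:n_max) {
    if (t_test_power(n, d, alpha, tails) >= power) return(n)
  }
  stop_invalid("iteration cap reached: power ", power,
               " not attainable with d = ", d, " within n <= ", n_max)
}
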