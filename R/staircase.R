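# Adaptive matrix-test staircase, simulated against a logistic virtual
# listener. Each sentence carries five scoreable words; the presented SNR
# moves against the signed difference between the observed proportion
# correct and the target proportion, with a geometrically shrinking step.

#' Create a logistic virtual listener
#'
#' The listener's word-recognition probability follows a logistic
#' psychometric function
#' `p(snr) = 1 / (1 + exp(-4 * slope * (snr - srt50)))`,
#' so `p(srt50) = 0.5` and `slope` is the probability change per dB at the
#' midpoint.
#'
#' @param srt50_db SNR (dB) at 50% word intelligibility.
#' @param slope_per_db Midpoint slope in probability per dB, in (0, 0.5].
#' @return An object of class `virtual_listener`.
#' @export
virtual_listener <- function(srt50_db, slope_per_db = 0.15) {
  if (!is.finite(srt50_db))
    stop_invalid("srt50_db must be finite")
  if (!(slope_per_db > 0 && slope_per_db <= 0.5))
    stop_invalid("slope_per_db must be in (0, 0.5]")
  structure(list(srt50_db = srt50_db, slope_per_db = slope_per_db),
            class = "virtual_listener")
}

#' Psychometric function of a virtual listener
#'
#' @param listener A [virtual_listener()].
#' @param snr_db SNR(s) in dB.
#' @return Word-recognition probability in (0, 1).
#' @export
psychometric <- function(listener, snr_db) {
  stopifnot(inherits(listener, "virtual_listener"))
  1 / (1 + exp(-4 * listener$slope_per_db * (snr_db - listener$srt50_db)))
}

#' Simulate the listener's response to one sentence
#'
#' Number of correctly repeated words out of the five word slots, drawn
#' binomially at the listener's recognition probability for the presented
#' SNR.
#'
#' @inheritParams psychometric
#' @param n_words Words per sentence (default 5).
#' @return Integer count in `0:n_words`.
#' @export
respond_sentence <- function(listener, snr_db, n_words = 5) {
  stats::rbinom(1, n_words, psychometric(listener, snr_db))
}

#' Run one adaptive staircase and read off the SRT
#'
#' Sentences start at `start_snr_db`; after sentence `i` the SNR moves by
#' `-step_i * (c_i/5 - target) / 0.5` dB where `c_i` is the number of words
#' correct and `step_i = max(step0 * step_decay^i, step_floor)`. The SRT
#' estimate is the SNR presented at the final (20th) sentence.
#'
#' @inheritParams psychometric
#' @param target Target proportion correct, typically 0.5 or 0.8; must lie
#'   in (0, 1).
#' @param n_sentences Sentences per list (default 20).
#' @param start_snr_db Starting SNR in dB (default 0).
#' @param step0 Initial step size in dB.
#' @param step_decay Geometric decay per sentence.
#' @param step_floor Minimum step size in dB.
#' @param n_words Words per sentence.
#' @return An object of class `staircase_result`: list with `target`,
#'   `snr_track` (length `n_sentences`), `words_correct`, `srt_db`.
#' @export
run_staircase <- function(listener, target, n_sentences = 20,
                          start_snr_db = 0, step0 = 4, step_decay = 0.8,
                          step_floor = 1, n_words = 5) {
  if (!(is.numeric(target) && length(target) == 1 && target > 0 && target < 1))
    stop_invalid("invalid configuration: target must lie strictly in (0, 1)")
  stopifnot(n_sentences >= 1)
  snr <- numeric(n_sentences)
  correct <- integer(n_sentences)
  snr[1] <- start_snr_db
  for (i in seq_len(n_sentences)) {
    correct[i] <- respond_sentence(listener, snr[i], n_words)
    if (i < n_sentences) {
      step <- max(step0 * step_decay^i, step_floor)
      snr[i + 1] <- snr[i] - step * (correct[i] / n_words - target) / 0.5
    }
  }
  structure(
    list(target = target, snr_track = snr, words_correct = correct,
         srt_db = snr[n_sentences]),
    class = "staircase_result"
  )
}

#' @export
print.staircase_result <- function(x, ...) {
  cat(sprintf("Staircase (target %.0f%%): SRT = %.2f dB SNR after %d sentences\n",
              100 * x$target, x$srt_db, length(x$snr_track)))
  invisible(x)
}

#' Simulate repeated SRT measurements
#'
#' Convenience wrapper running [run_staircase()] `n_runs` times under a
#' reproducible seed.
#'
#' @inheritParams run_staircase
#' @param n_runs Number of independent staircases.
#' @param seed Optional master seed.
#' @param ... Passed to [run_staircase()].
#' @return Data frame with one row per run: `run`, `target`, `srt_db`.
#' @export
simulate_srt_experiment <- function(listener, target, n_runs = 200,
                                    seed = NULL, ...) {
  srt <- with_seed(seed, vapply(seq_len(n_runs), function(i) {
    run_staircase(listener, target, ...)$srt_db
  }, numeric(1)))
  data.frame(run = seq_len(n_runs), target = target, srt_db = srt)
}
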