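# Noise vocoding: band-split speech, extract per-band Hilbert envelopes,
# re-impose them on band-limited noise carriers, and sum. Spectral fine
# structure of the input is destroyed; only the per-band amplitude
# envelopes survive, so intelligibility is controlled by the channel count.

#' Design a logarithmic vocoder filterbank
#'
#' Band edges are geometrically (log-) spaced between `f_lo` and `f_hi`, so
#' the ratio of adjacent edges is constant: `(f_hi/f_lo)^(1/n_channels)`.
#' Each band is an order-`order` Butterworth band-pass applied zero-phase
#' with unity passband gain.
#'
#' @param n_channels Number of analysis channels (>= 2; 6 and 16 are the
#'   conditions used for the listening experiment).
#' @param f_lo,f_hi Overall passband bounds in Hz, `0 < f_lo < f_hi`.
#' @param order Butterworth order per band edge (default 4).
#' @param sample_rate_hz Optional; if given, `f_hi` must lie below Nyquist.
#' @return An object of class `filterbank` with fields `n_channels`,
#'   `edges_hz` (length `n_channels + 1`), `order`, `f_lo`, `f_hi`.
#' @examples
#' design_filterbank(6, 80, 8000)$edges_hz
#' @export
design_filterbank <- function(n_channels, f_lo = 80, f_hi = 8000, order = 4,
                              sample_rate_hz = NULL) {
  if (!is.numeric(n_channels) || n_channels < 2 || n_channels != round(n_channels))
    stop_invalid("n_channels must be an integer >= 2")
  if (!(f_lo > 0 && f_hi > f_lo))
    stop_invalid("need 0 < f_lo < f_hi")
  if (!is.null(sample_rate_hz) && f_hi >= sample_rate_hz / 2)
    stop_invalid("invalid configuration: f_hi (", f_hi,
                 " Hz) is at or above the Nyquist frequency (",
                 sample_rate_hz / 2, " Hz)")
  edges <- f_lo * (f_hi / f_lo)^(seq(0, n_channels) / n_channels)
  structure(
    list(n_channels = as.integer(n_channels), edges_hz = edges,
         order = as.integer(order), f_lo = f_lo, f_hi = f_hi),
    class = "filterbank"
  )
}

#' @export
print.filterbank <- function(x, ...) {
  cat("Vocoder filterbank:", x$n_channels, "log-spaced channels,",
      round(x$f_lo), "-", round(x$f_hi), "Hz, Butterworth order", x$order, "\n")
  cat("Edges (Hz):", paste(round(x$edges_hz, 1), collapse = ", "), "\n")
  invisible(x)
}

# Per-channel zero-phase gains for a filterbank at a given length/rate.
bank_gains <- function(bank, n, sample_rate_hz) {
  f <- fft_bin_freqs(n, sample_rate_hz)
  lapply(seq_len(bank$n_channels), function(ch) {
    butter_bandpass_gain(f, bank$edges_hz[ch], bank$edges_hz[ch + 1], bank$order)
  })
}

#' Noise-vocode a signal
#'
#' For each channel the signal is band-passed, its Hilbert envelope taken and
#' divided by the number of channels, and the result used to amplitude-
#' modulate a band-passed white Gaussian noise carrier. The modulated bands
#' are summed.
#'
#' @param signal Numeric waveform (finite).
#' @param bank A [design_filterbank()] object.
#' @param sample_rate_hz Sampling rate of `signal` in Hz; the filterbank's
#'   `f_hi` must lie below Nyquist.
#' @param seed Optional integer seed for the noise carrier; the same seed
#'   gives a bit-identical carrier and output.
#' @param envelope_lowpass_hz Optional envelope smoothing cut-off in Hz
#'   (4th-order Butterworth low-pass applied to each band envelope);
#'   `NULL` (default) uses the raw Hilbert envelope.
#' @return Vocoded waveform, same length as `signal`.
#' @export
vocode_signal <- function(signal, bank, sample_rate_hz, seed = NULL,
                          envelope_lowpass_hz = NULL) {
  stopifnot(inherits(bank, "filterbank"), is.numeric(signal))
  if (!all(is.finite(signal))) stop_invalid("signal contains non-finite values")
  if (bank$f_hi >= sample_rate_hz / 2)
    stop_invalid("invalid configuration: filterbank f_hi is at or above Nyquist")
  n <- length(signal)
  gains <- bank_gains(bank, n, sample_rate_hz)
  carrier <- with_seed(seed, stats::rnorm(n))
  f <- fft_bin_freqs(n, sample_rate_hz)
  lp <- if (!is.null(envelope_lowpass_hz))
    butter_lowpass_gain(f, envelope_lowpass_hz) else NULL
  out <- numeric(n)
  for (g in gains) {
    env <- envelope_fft(signal, g) / bank$n_channels
    if (!is.null(lp)) env <- filter_fft(env, lp)
    out <- out + env * filter_fft(carrier, g)
  }
  out
}

#' Assemble a 6-s sentence-in-babble trial at a given SNR
#'
#' The trial runs 6 s: background noise throughout, with the (vocoded)
#' sentence occupying 1.0-4.5 s. Speech and babble are first scaled to a
#' common RMS (the babble to `noise_rms`, a fixed reference standing in for
#' the constant 65 dB SPL presentation level), then the speech is scaled by
#' `10^(snr_db/20)`. Sentences shorter than 3.5 s are padded symmetrically
#' with silence; longer ones are an error unless `trim = TRUE`.
#'
#' @param vocoded_speech Speech waveform (<= 3.5 s unless `trim`).
#' @param vocoded_babble Background waveform, at least 6 s long (trimmed to
#'   6 s).
#' @param snr_db Signal-to-noise ratio in dB.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param condition_label Optional label, e.g. `"6ch50% SRT"`.
#' @param noise_rms Full-scale RMS of the background noise (default 0.05).
#' @param trim If `TRUE`, speech longer than 3.5 s is trimmed; otherwise it
#'   is an error.
#' @return An object of class `audio_trial`: list with `samples`,
#'   `sample_rate_hz`, `snr_db`, `condition_label` and segment boundaries
#'   `t_noise_on = 0`, `t_speech_on = 1`, `t_speech_off = 4.5`, `t_end = 6`.
#' @export
assemble_trial <- function(vocoded_speech, vocoded_babble, snr_db,
                           sample_rate_hz, condition_label = NA_character_,
                           noise_rms = 0.05, trim = FALSE) {
  stopifnot(is.finite(snr_db))
  fs <- sample_rate_hz
  n_speech_max <- round(3.5 * fs)
  n_total <- round(6 * fs)
  if (length(vocoded_speech) > n_speech_max) {
    if (!trim)
      stop_invalid("duration error: speech is longer than 3.5 s (",
                   length(vocoded_speech) / fs, " s); set trim = TRUE to cut")
    vocoded_speech <- vocoded_speech[seq_len(n_speech_max)]
  }
  if (length(vocoded_babble) < n_total)
    stop_invalid("background must be at least 6 s long")
  noise <- vocoded_babble[seq_len(n_total)]
  noise <- noise * (noise_rms / rms(noise))

  pad <- n_speech_max - length(vocoded_speech)
  pad_l <- floor(pad / 2)
  speech <- c(numeric(pad_l), vocoded_speech, numeric(pad - pad_l))
  nz <- speech != 0
  if (any(nz)) {
    speech <- speech * (noise_rms / rms(speech[nz])) * db_to_amplitude(snr_db)
  }
  samples <- noise
  idx <- round(1 * fs) + seq_len(n_speech_max)
  samples[idx] <- samples[idx] + speech

  structure(
    list(samples = samples, sample_rate_hz = fs, snr_db = snr_db,
         condition_label = condition_label,
         t_noise_on = 0, t_speech_on = 1, t_speech_off = 4.5, t_end = 6),
    class = "audio_trial"
  )
}

#' @export
print.audio_trial <- function(x, ...) {
  cat("Audio trial: 6 s @", x$sample_rate_hz, "Hz, SNR", x$snr_db, "dB",
      if (!is.na(x$condition_label)) paste0("(", x$condition_label, ")"), "\n")
  invisible(x)
}

#' Render a batch of vocoded trials to WAV files with a manifest
#'
#' Vocodes the given speech and babble once per trial (fresh carrier seed per
#' trial), assembles each trial at its SNR, writes mono float WAV files and a
#' CSV manifest (trial index, condition label, SNR, seed, file path).
#'
#' @param speech,babble Raw (unvocoded) waveforms; babble >= 6 s.
#' @param snr_db Vector of per-trial SNRs in dB.
#' @param bank A [design_filterbank()] object.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param out_dir Output directory (created if needed).
#' @param condition_label Label stored in trials and manifest.
#' @param seed Master seed; per-trial carrier seeds are derived from it.
#' @return The manifest data frame, invisibly.
#' @export
write_trial_batch <- function(speech, babble, snr_db, bank, sample_rate_hz,
                              out_dir, condition_label = NA_character_,
                              seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", length(snr_db))
  for (i in seq_along(snr_db)) {
    trial_seed <- derive_seed(seed, condition_label, i)
    vs <- vocode_signal(speech, bank, sample_rate_hz, seed = trial_seed)
    vb <- vocode_signal(babble, bank, sample_rate_hz,
                        seed = derive_seed(trial_seed, "babble"))
    trial <- assemble_trial(vs, vb, snr_db[i], sample_rate_hz,
                            condition_label = condition_label)
    path <- file.path(out_dir, sprintf("trial_%03d.wav", i))
    write_wav(trial$samples, path, sample_rate_hz)
    rows[[i]] <- data.frame(trial = i, condition_label = condition_label,
                            snr_db = snr_db[i], seed = trial_seed,
                            path = path, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
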