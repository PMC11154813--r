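# File interchange: delimited sample tables for EEG and pupil data, JSON
# event sidecars, float WAV audio, and YAML run configuration. Tables are
# comma-separated UTF-8 with one header row; units are embedded in column
# names (time in ms, EEG in microvolts, pupil in px).

check_numeric_column <- function(x, col, path) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x) & x != "")
  if (length(bad))
    stop_invalid("parse error in ", path, ", column ", col, ", row ", bad[1],
                 ": '", x[bad[1]], "' is not numeric")
  v
}

#' Write an EEG recording as a delimited table plus an event sidecar
#'
#' The CSV has `time_ms` followed by one column per channel (microvolts).
#' Trial onsets and the condition label go into a JSON sidecar.
#'
#' @param rec An [eeg_recording()].
#' @param path CSV output path.
#' @param events_path Optional JSON sidecar path.
#' @param condition_label Optional condition label stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_eeg_table <- function(rec, path, events_path = NULL,
                            condition_label = NA_character_) {
  stopifnot(inherits(rec, "eeg_recording"))
  tab <- data.frame(
    time_ms = (seq_len(nrow(rec$samples)) - 1) / rec$sample_rate_hz * 1000,
    rec$samples, check.names = FALSE)
  utils::write.csv(tab, path, row.names = FALSE)
  if (!is.null(events_path)) {
    jsonlite::write_json(
      list(sample_rate_hz = rec$sample_rate_hz,
           reference_label = rec$reference_label,
           trial_onset_sample = rec$trial_onsets,
           condition_label = condition_label),
      events_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read an EEG recording from a delimited table
#'
#' @param path CSV with `time_ms` then channel columns.
#' @param events_path Optional JSON sidecar written by [write_eeg_table()].
#' @param require_channels Channels that must be present (default the
#'   parietal set); a missing one is an error naming the label.
#' @return An [eeg_recording()].
#' @export
read_eeg_table <- function(path, events_path = NULL,
                           require_channels = parietal_channels()) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  tab <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character")
  if (!"time_ms" %in% names(tab))
    stop_invalid("missing column time_ms in ", path)
  missing <- setdiff(require_channels, names(tab))
  if (length(missing))
    stop_invalid("missing channel column(s) in ", path, ": ",
                 paste(missing, collapse = ", "))
  time_ms <- check_numeric_column(tab$time_ms, "time_ms", path)
  chans <- setdiff(names(tab), "time_ms")
  samples <- vapply(chans, function(cn)
    check_numeric_column(tab[[cn]], cn, path), numeric(nrow(tab)))
  colnames(samples) <- chans
  fs <- 1000 / stats::median(diff(time_ms))
  onsets <- integer(0)
  ref <- "A2"
  if (!is.null(events_path)) {
    ev <- jsonlite::read_json(events_path, simplifyVector = TRUE)
    if (!is.null(ev$sample_rate_hz)) fs <- ev$sample_rate_hz
    if (!is.null(ev$trial_onset_sample)) onsets <- as.integer(ev$trial_onset_sample)
    if (!is.null(ev$reference_label)) ref <- ev$reference_label
  }
  eeg_recording(samples, fs, trial_onsets = onsets, reference_label = ref)
}

#' Write a pupil trace as a delimited sample report
#'
#' Columns: `TIME_MS`, `PUPIL_SIZE_PX`, `VALID` (0/1), in the style of an
#' eye-tracker sample report.
#'
#' @param trace A [pupil_trace()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_pupil_table <- function(trace, path) {
  stopifnot(inherits(trace, "pupil_trace"))
  utils::write.csv(
    data.frame(TIME_MS = trace$time_ms,
               PUPIL_SIZE_PX = trace$diameter_px,
               VALID = as.integer(trace$valid)),
    path, row.names = FALSE)
  invisible(path)
}

#' Read a pupil trace from a delimited sample report
#'
#' Accepts `TIME_MS`/`PUPIL_SIZE_PX`/`VALID` columns (case-insensitive;
#' `TIME` and `PUPIL_SIZE` also accepted). Samples with `VALID = 0` or
#' non-positive size are marked invalid; blink intervals are then
#' reconstructed from invalid runs by [detect_blinks()].
#'
#' @param path CSV input path.
#' @param trial_onset_ms Stimulus onset in ms (default 0).
#' @return A [pupil_trace()].
#' @export
read_pupil_table <- function(path, trial_onset_ms = 0) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  tab <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  names(tab) <- toupper(names(tab))
  tcol <- intersect(c("TIME_MS", "TIME"), names(tab))[1]
  pcol <- intersect(c("PUPIL_SIZE_PX", "PUPIL_SIZE"), names(tab))[1]
  if (is.na(tcol) || is.na(pcol))
    stop_invalid("missing TIME/PUPIL_SIZE columns in ", path)
  time_ms <- check_numeric_column(tab[[tcol]], tcol, path)
  size <- check_numeric_column(tab[[pcol]], pcol, path)
  valid <- if ("VALID" %in% names(tab))
    check_numeric_column(tab$VALID, "VALID", path) != 0
  else rep(TRUE, length(size))
  valid <- valid & size > 0
  size[!valid] <- 1e-6  # placeholder; these samples are interpolated away
  pupil_trace(time_ms, size, valid, trial_onset_ms = trial_onset_ms)
}

#' Write a mono float WAV file
#'
#' 32-bit IEEE-float PCM, single channel.
#'
#' @param samples Numeric waveform.
#' @param path Output path.
#' @param sample_rate_hz Sampling rate in Hz.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate_hz) {
  n <- length(samples)
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 4L * n
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")   # IEEE float
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(sample_rate_hz), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate_hz * 4), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")   # block align
  writeBin(32L, con, size = 2, endian = "little")  # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(as.numeric(samples), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a mono float WAV file written by [write_wav()]
#'
#' @param path Input path.
#' @return List with `samples` and `sample_rate_hz`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop_invalid("not a RIFF/WAV file: ", path)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop_invalid("not a WAV file: ", path)
  fs <- NULL
  fmt <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop_invalid("no data chunk in ", path)
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      fs <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, "raw", n = size - 8))
    } else if (id == "data") {
      if (is.null(fmt) || fmt[1] != 3 || fmt[2] != 1)
        stop_invalid("only mono IEEE-float WAV is supported")
      samples <- readBin(con, numeric(), n = size / 4, size = 4,
                         endian = "little")
      return(list(samples = samples, sample_rate_hz = fs))
    } else {
      invisible(readBin(con, "raw", n = size))
    }
  }
}

#' Assemble a run configuration, optionally from a YAML file
#'
#' Built-in defaults (seed, output directory, filter and window settings,
#' QC threshold, condition labels) are overridden first by the YAML file,
#' then by `...`.
#'
#' @param path Optional YAML file.
#' @param ... Named overrides.
#' @return List of class `run_config` with a `config_hash` attribute.
#' @export
run_config <- function(path = NULL, ...) {
  config <- list(
    seed = 1,
    out_dir = "effortlab-out",
    alpha_band_hz = c(8, 12),
    notch_hz = 50,
    windows = alpha_windows(),
    qc_threshold_uv = 80,
    conditions = listening_conditions(),
    staircase = list(slope_per_db = 0.15, n_runs_per_subject = 1),
    cohort = list()
  )
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    config[names(user)] <- user
  }
  dots <- list(...)
  config[names(dots)] <- dots
  if (is.null(config$seed)) stop_invalid("config must carry a seed")
  w <- unlist(config$windows)
  if (any(w < -0.5) || any(w > 6))
    stop_invalid("analysis windows must lie within [-0.5, 6] s")
  structure(config, class = "run_config",
            config_hash = object_hash(config))
}
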