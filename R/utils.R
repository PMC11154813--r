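#' Root-mean-square amplitude
#'
#' @param x Numeric vector.
#' @return `sqrt(mean(x^2))`.
#' @export
rms <- function(x) {
  stopifnot(is.numeric(x), length(x) > 0)
  sqrt(mean(x^2))
}

#' Convert a level difference in dB to an amplitude ratio
#'
#' @param db Level in dB.
#' @return `10^(db/20)`.
#' @export
db_to_amplitude <- function(db) 10^(db / 20)

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed = NULL` runs `code` on the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Derive a reproducible child seed from a master seed and string labels
#'
#' Deterministic polynomial hash; the result is in `[1, 2^31 - 2]` so it is a
#' valid R integer seed. Used to give every subject/condition/modality its own
#' independent but reproducible stream.
#'
#' @param master Integer master seed.
#' @param ... Character or numeric labels mixed into the hash.
#' @return A single integer seed.
#' @export
derive_seed <- function(master, ...) {
  m <- 2147483563
  h <- as.numeric(master) %% m
  for (part in list(...)) {
    for (code in utf8ToInt(paste0(as.character(part), "|"))) {
      h <- (h * 31 + code) %% m
    }
  }
  as.integer(h %% (m - 2) + 1)
}

# Stable short hash of an arbitrary R object (used for config provenance).
object_hash <- function(x) {
  txt <- paste(deparse(x), collapse = "\n")
  m <- 2147483563
  h <- 0
  for (code in utf8ToInt(txt)) h <- (h * 31 + code) %% m
  sprintf("%08x", as.integer(h))
}

stop_invalid <- function(...) stop(..., call. = FALSE)
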