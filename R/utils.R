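# Small numeric helpers shared across modules.

#' Convert a linear amplitude ratio to decibels
#' @param x positive amplitude ratio
#' @return `20 * log10(x)`
#' @export
amp_to_db <- function(x) 20 * log10(x)

#' Convert decibels to a linear amplitude ratio
#' @param db decibel value
#' @return `10^(db / 20)`
#' @export
db_to_amp <- function(db) 10^(db / 20)

#' Fraction of signal energy inside a frequency band
#'
#' One-sided periodogram energy in `[lo_hz, hi_hz)` divided by total energy.
#' Used as the independent oracle for the band flags of synthetic clicks.
#'
#' @param x numeric waveform
#' @param rate_hz sampling rate in Hz
#' @param lo_hz,hi_hz band edges in Hz (half-open, `hi_hz` capped at Nyquist)
#' @return a proportion in \[0, 1\]
#' @export
band_energy_fraction <- function(x, rate_hz, lo_hz, hi_hz) {
  stopifnot(is.numeric(x), length(x) > 1, lo_hz < hi_hz)
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  # one-sided spectrum: bins 1..floor(n/2)+1 cover 0..Nyquist
  half <- seq_len(floor(n / 2) + 1)
  p <- p[half]
  f <- (half - 1) * rate_hz / n
  tot <- sum(p)
  if (tot == 0) return(0)
  sum(p[f >= lo_hz & f < hi_hz]) / tot
}

# Magnitude of the analytic signal (Hilbert envelope) via FFT.
analytic_magnitude <- function(x) {
  n <- length(x)
  if (n == 0) return(numeric(0))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# Centred moving average with shrinking windows at the edges (cumsum-based).
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width == 1L || length(x) < 2) return(x)
  n <- length(x)
  half <- width %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Root-mean-square.
rms <- function(x) sqrt(mean(x^2))

# Deterministic 32-bit-safe seed derived from a master seed and a string id;
# adding recordings never perturbs the seeds of existing ones.
derive_seed <- function(master_seed, id) {
  h <- sum(utf8ToInt(as.character(id)) * seq_along(utf8ToInt(as.character(id))))
  as.integer((as.numeric(master_seed) * 7919 + h * 104729) %% 2147483647)
}

# Run an expression under a local RNG seed without disturbing the caller's
# RNG state. seed = NULL runs the expression as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
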