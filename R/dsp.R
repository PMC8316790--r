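# Downsampling chain (Butterworth high-pass -> FIR anti-alias -> decimation)
# and STFT spectrogram. Filter design is done in-package (bilinear-transform
# Butterworth, Kaiser-windowed-sinc FIR); the inner filtering loops run
# through stats::filter / stats::fft, which are C-backed.

# Polynomial coefficients (descending powers handled implicitly: coefs[1] is
# the leading 1) from a set of roots, by repeated convolution.
poly_from_roots <- function(roots) {
  coefs <- 1 + 0i
  for (r in roots) coefs <- c(coefs, 0) - c(0, r * coefs)
  coefs
}

# Digital Butterworth high-pass design by bilinear transform.
# Returns list(b, a) transfer-function coefficients with a[1] = 1.
butter_highpass_coef <- function(order, cutoff_hz, rate_hz) {
  stopifnot(order >= 1, cutoff_hz > 0)
  if (cutoff_hz >= rate_hz / 2)
    stop("high-pass cutoff (", cutoff_hz, " Hz) must be below the Nyquist frequency (",
         rate_hz / 2, " Hz)")
  k <- seq_len(order)
  # unit-cutoff analog low-pass prototype poles (left half-plane)
  p_lp <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  warped <- 2 * rate_hz * tan(pi * cutoff_hz / rate_hz)
  p <- warped / p_lp                  # LP -> HP transform s -> warped/s
  fs2 <- 2 * rate_hz
  pd <- (fs2 + p) / (fs2 - p)         # bilinear transform of poles
  zd <- rep(1 + 0i, order)            # analog zeros at s = 0 map to z = +1
  a <- Re(poly_from_roots(pd))
  b <- Re(poly_from_roots(zd))
  # normalise gain to 1 at Nyquist (z = -1)
  hz_at <- function(coefs, z) sum(coefs * z^(-(seq_along(coefs) - 1)))
  g <- Mod(hz_at(a, -1 + 0i)) / Mod(hz_at(b, -1 + 0i))
  list(b = g * b, a = a)
}

# Causal IIR filtering y = filter(b, a, x) via stats::filter:
# FIR part by one-sided convolution, AR part by the recursive filter.
iir_filter <- function(b, a, x) {
  b <- b / a[1]; a <- a / a[1]
  nb <- length(b)
  v <- stats::filter(c(rep(0, nb - 1), x), b, method = "convolution", sides = 1)
  v <- as.numeric(v)[nb:(nb - 1 + length(x))]
  if (length(a) > 1) {
    y <- stats::filter(v, -a[-1], method = "recursive")
    as.numeric(y)
  } else v
}

#' Fourth-order Butterworth high-pass filter
#'
#' Causal (forward-only) high-pass used before downsampling to strip
#' low-frequency ambient and flow noise; default cutoff 15 kHz.
#'
#' @param rec a `pam_recording`
#' @param cutoff_hz -3 dB cutoff frequency in Hz
#' @param order filter order
#' @return a filtered `pam_recording` with the same length and rate
#' @export
butterworth_highpass <- function(rec, cutoff_hz = 15000, order = 4) {
  stopifnot(inherits(rec, "pam_recording"))
  coef <- butter_highpass_coef(order, cutoff_hz, rec$rate_hz)
  out <- rec
  out$samples <- iir_filter(coef$b, coef$a, rec$samples)
  out
}

# Kaiser window of length n with shape beta (besselI is base R).
kaiser_window <- function(n, beta) {
  m <- n - 1
  t <- (0:m - m / 2) / (m / 2)
  besselI(beta * sqrt(pmax(0, 1 - t^2)), 0) / besselI(beta, 0)
}

# Kaiser-windowed-sinc linear-phase FIR low-pass. Transition band
# 0.9-1.05 x cutoff_hz, stopband attenuation ~70 dB (spec floor is 60 dB,
# passband ripple well under 0.5 dB). Returns odd-length taps.
fir_lowpass_taps <- function(cutoff_hz, rate_hz, atten_db = 70) {
  trans_lo <- 0.9 * cutoff_hz
  trans_hi <- 1.05 * cutoff_hz
  dw <- 2 * pi * (trans_hi - trans_lo) / rate_hz
  beta <- if (atten_db > 50) 0.1102 * (atten_db - 8.7) else
    0.5842 * (atten_db - 21)^0.4 + 0.07886 * (atten_db - 21)
  n <- ceiling((atten_db - 7.95) / (2.285 * dw)) + 1
  if (n %% 2 == 0) n <- n + 1
  fc <- (trans_lo + trans_hi) / 2 / rate_hz   # normalised (cycles/sample)
  m <- n - 1
  k <- 0:m - m / 2
  h <- 2 * fc * ifelse(k == 0, 1, sin(2 * pi * fc * k) / (2 * pi * fc * k))
  h <- h * kaiser_window(n, beta)
  h / sum(h)
}

# Zero-delay application of a linear-phase FIR by FFT convolution; the
# (n-1)/2-sample group delay is removed so output aligns with input.
fir_filter_centered <- function(h, x) {
  n <- length(x); nh <- length(h)
  nfft <- stats::nextn(n + nh - 1, 2)
  X <- stats::fft(c(x, rep(0, nfft - n)))
  H <- stats::fft(c(h, rep(0, nfft - nh)))
  y <- Re(stats::fft(X * H, inverse = TRUE)) / nfft
  delay <- (nh - 1) / 2
  y[(delay + 1):(delay + n)]
}

#' Anti-aliasing FIR low-pass filter
#'
#' Linear-phase Kaiser-windowed-sinc low-pass ahead of decimation:
#' stopband (above `1.05 * target_nyquist_hz`) attenuation >= 60 dB, passband
#' (below `0.9 * target_nyquist_hz`) ripple <= 0.5 dB. The group delay is
#' compensated so the output is time-aligned with the input.
#'
#' @param rec a `pam_recording`
#' @param target_nyquist_hz the Nyquist frequency of the intended target rate
#' @return a filtered `pam_recording` with the same length and rate
#' @export
antialias_lowpass <- function(rec, target_nyquist_hz) {
  stopifnot(inherits(rec, "pam_recording"))
  if (target_nyquist_hz >= rec$rate_hz / 2)
    stop("target Nyquist must be below the recording's Nyquist frequency")
  h <- fir_lowpass_taps(target_nyquist_hz, rec$rate_hz)
  out <- rec
  out$samples <- fir_filter_centered(h, rec$samples)
  out
}

#' Downsample a recording through the anti-aliasing chain
#'
#' Applies the 15 kHz fourth-order Butterworth high-pass, the FIR anti-alias
#' low-pass at the new Nyquist frequency, then keeps every k-th sample
#' (k = rate / target), starting at sample 1.
#'
#' @param rec a `pam_recording` (typically 192 kHz)
#' @param target_rate_hz target sampling rate; must divide the source rate
#' @param highpass_hz Butterworth high-pass cutoff (15 kHz as used ahead of
#'   automatic detection); set to `NULL` to skip the high-pass
#' @return a `pam_recording` at `target_rate_hz`, length `ceiling(n / k)`
#' @export
downsample_chain <- function(rec, target_rate_hz, highpass_hz = 15000) {
  stopifnot(inherits(rec, "pam_recording"))
  if (rec$rate_hz %% target_rate_hz != 0)
    stop("source rate ", rec$rate_hz, " is not an integer multiple of target rate ",
         target_rate_hz)
  k <- rec$rate_hz %/% target_rate_hz
  filtered <- if (!is.null(highpass_hz)) butterworth_highpass(rec, highpass_hz) else rec
  filtered <- antialias_lowpass(filtered, target_rate_hz / 2)
  out <- filtered
  out$samples <- filtered$samples[seq(1, length(filtered$samples), by = k)]
  out$rate_hz <- target_rate_hz
  out
}

#' Short-time Fourier transform spectrogram
#'
#' Hann-windowed STFT magnitude, 512-point frames with 50% overlap by default
#' (the settings used to inspect click spectra). Frames are computed in
#' chunks to bound memory on long recordings.
#'
#' @param rec a `pam_recording`
#' @param nfft frame length in samples
#' @param overlap fractional frame overlap in \[0, 1)
#' @param window window name; only `"hann"` is implemented
#' @return an object of class `"pam_spectrogram"`: list with `mag`
#'   (linear magnitude, `nfft/2 + 1` frequency bins x frames), `freq_hz`,
#'   `time_s` (frame centres), `window`, `nfft`, `overlap`, `rate_hz`
#' @export
spectrogram <- function(rec, nfft = 512, overlap = 0.5, window = "hann") {
  stopifnot(inherits(rec, "pam_recording"))
  if (window != "hann") stop("only the Hann window is implemented")
  x <- rec$samples
  if (length(x) < nfft)
    stop("recording shorter than one analysis frame (", nfft, " samples)")
  hop <- as.integer(round(nfft * (1 - overlap)))
  stopifnot(hop >= 1)
  starts <- seq(1L, length(x) - nfft + 1L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nfft - 1)) / (nfft - 1))
  nbin <- nfft %/% 2 + 1L
  mag <- matrix(0, nrow = nbin, ncol = length(starts))
  chunk <- 4096L
  for (c0 in seq(1L, length(starts), by = chunk)) {
    cols <- c0:min(c0 + chunk - 1L, length(starts))
    frames <- x[outer(0:(nfft - 1L), starts[cols], `+`)]
    dim(frames) <- c(nfft, length(cols))
    frames <- frames * w
    sp <- stats::mvfft(frames)
    mag[, cols] <- Mod(sp[seq_len(nbin), , drop = FALSE])
  }
  structure(
    list(mag = mag,
         freq_hz = (seq_len(nbin) - 1) * rec$rate_hz / nfft,
         time_s = (starts - 1 + nfft / 2) / rec$rate_hz,
         window = window, nfft = nfft, overlap = overlap,
         rate_hz = rec$rate_hz),
    class = "pam_spectrogram"
  )
}

#' @export
print.pam_spectrogram <- function(x, ...) {
  cat(sprintf("<pam_spectrogram> %d bins x %d frames, %g Hz, nfft=%d, overlap=%.0f%%\n",
              nrow(x$mag), ncol(x$mag), x$rate_hz, x$nfft, 100 * x$overlap))
  invisible(x)
}
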