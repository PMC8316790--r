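# Synthetic soundscape generator: parametric broadband clicks arranged in
# echolocation click trains, snapping-shrimp-like impulsive interference and
# ambient noise, rendered at 192 kHz with exact ground truth. This is the
# stand-in for field recordings: every downstream stage (census, downsampling,
# detection, matching, GLMMs) is exercised against known truth.

#' Configuration of a synthetic soundscape
#'
#' Defaults describe a plausible bottlenose-dolphin recording: click trains
#' with inter-click intervals (ICIs) between 20 and 150 ms (echolocation
#' regime: ICI > 10 ms, trains broken by gaps > 0.2 s), broadband clicks of
#' ~150 us whose spectral support relative to the 24 and 48 kHz thresholds is
#' drawn per click (~400 us rendered support including the trailing low-band
#' tail), and white ambient noise. Band-flag probabilities default
#' per environment (lagoon 0.99 / 0.9999, open 0.86 / 0.996); these are
#' simulation truths chosen for the generator, not field estimates.
#'
#' @param duration_s recording length in seconds
#' @param rate_hz sampling rate (must be even; 192 kHz by default)
#' @param n_clicks total number of clicks to place; overrides `click_rate`
#' @param click_rate clicks per second used when `n_clicks` is `NULL`
#' @param ici_range_s inter-click interval range in seconds, within
#'   (0.01, 0.2\]
#' @param p_below24,p_below48 probabilities that a click carries supra-noise
#'   energy below 24 and 48 kHz; must satisfy `p_below24 <= p_below48`
#'   (a click seen below 24 kHz is necessarily seen below 48 kHz). `NULL`
#'   selects the per-environment default.
#' @param click_centroid_hz,click_bandwidth_hz centroid and full (6-sigma)
#'   spectral support of the main (high-frequency) click component
#' @param click_duration_us click support duration in microseconds
#' @param snap_rate_per_s Poisson rate of snapping-shrimp-like impulses
#' @param snr_db click peak amplitude over the RMS of the ambient noise in
#'   the 15-90 kHz band, in dB
#' @param noise_spectrum `"white"`, `"pink"`, or `"none"` for noiseless
#'   detector fixtures
#' @param environment `"lagoon"` or `"open"`
#' @param seed integer seed making the rendering reproducible
#' @return an object of class `"synth_config"`
#' @export
synth_config <- function(duration_s = 60, rate_hz = 192000,
                         n_clicks = NULL, click_rate = 12,
                         ici_range_s = c(0.02, 0.15),
                         p_below24 = NULL, p_below48 = NULL,
                         click_centroid_hz = 70000, click_bandwidth_hz = 36000,
                         click_duration_us = 400,
                         snap_rate_per_s = 0, snr_db = 25,
                         noise_spectrum = c("white", "pink", "none"),
                         environment = c("lagoon", "open"), seed = 1L) {
  environment <- match.arg(environment)
  noise_spectrum <- match.arg(noise_spectrum)
  if (is.null(p_below24))
    p_below24 <- if (environment == "lagoon") 0.99 else 0.86
  if (is.null(p_below48))
    p_below48 <- if (environment == "lagoon") 0.9999 else 0.996
  stopifnot(duration_s > 0, rate_hz %% 2 == 0,
            length(ici_range_s) == 2)
  if (!(ici_range_s[1] > 0.01 && ici_range_s[1] < ici_range_s[2] &&
        ici_range_s[2] <= 0.2))
    stop("ici_range_s must satisfy 0.01 < min < max <= 0.2 (echolocation regime)")
  if (!(p_below24 >= 0 && p_below24 <= p_below48 && p_below48 <= 1))
    stop("band-flag probabilities must satisfy 0 <= p_below24 <= p_below48 <= 1")
  if (!is.null(n_clicks)) stopifnot(n_clicks >= 0)
  structure(
    list(duration_s = duration_s, rate_hz = rate_hz, n_clicks = n_clicks,
         click_rate = click_rate, ici_range_s = ici_range_s,
         p_below24 = p_below24, p_below48 = p_below48,
         click_centroid_hz = click_centroid_hz,
         click_bandwidth_hz = click_bandwidth_hz,
         click_duration_us = click_duration_us,
         snap_rate_per_s = snap_rate_per_s, snr_db = snr_db,
         noise_spectrum = noise_spectrum, environment = environment,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

# One Gaussian-enveloped carrier: spectral sigma = bandwidth/6, time-domain
# sigma = 1/(2*pi*sigma_f), rendered over the given support.
gauss_component <- function(t, centroid_hz, bandwidth_hz) {
  sigma_f <- bandwidth_hz / 6
  sigma_t <- 1 / (2 * pi * sigma_f)
  exp(-t^2 / (2 * sigma_t^2)) * cos(2 * pi * centroid_hz * t)
}

#' Render one parametric broadband click
#'
#' A Gaussian-enveloped carrier (chirpless) at `centroid_hz` plus separately
#' gained mid-band and low-band components, giving independent control over
#' the click's energy above 48 kHz, in 24-48 kHz, and below 24 kHz — the
#' quantities the spectrogram census judges. The mid- and low-band components
#' trail the main pulse by 1/8 and 1/4 of the click duration, as off-axis
#' low-frequency click content does; this also keeps the components from
#' superposing at one instant, so peak normalisation does not dilute any
#' band's amplitude. `bandwidth_hz` is the full (6-sigma) spectral support of
#' each component. Peak |amplitude| is 1.
#'
#' @param centroid_hz centroid of the main component; must be below Nyquist
#' @param bandwidth_hz full spectral support of the main component
#' @param duration_us total rendered support in microseconds (>= 8 samples)
#' @param rate_hz sampling rate
#' @param low_band_gain_db gain of the low-band component relative to the main
#'   component's peak; `-Inf` omits it. Models off-axis low-frequency click
#'   content.
#' @param low_band_hz,low_band_bandwidth_hz low-band component location
#'   (default 19 kHz, support ~13-25 kHz, inside the 15 kHz high-pass
#'   passband and below the 24 kHz threshold)
#' @param mid_band_gain_db,mid_band_hz,mid_band_bandwidth_hz mid-band
#'   component (default 36 kHz, support ~27-45 kHz: between the thresholds)
#' @return numeric waveform of `round(duration_us * 1e-6 * rate_hz)` samples
#' @export
make_click <- function(centroid_hz, bandwidth_hz, duration_us, rate_hz,
                       low_band_gain_db = -Inf,
                       low_band_hz = 19000, low_band_bandwidth_hz = 12000,
                       mid_band_gain_db = -Inf,
                       mid_band_hz = 36000, mid_band_bandwidth_hz = 18000) {
  if (centroid_hz >= rate_hz / 2)
    stop("click centroid (", centroid_hz, " Hz) must be below the Nyquist frequency (",
         rate_hz / 2, " Hz)")
  stopifnot(bandwidth_hz > 0)
  n <- round(duration_us * 1e-6 * rate_hz)
  if (n < 8)
    stop("click duration ", duration_us,
         " us yields fewer than 8 samples at ", rate_hz, " Hz")
  t <- (seq_len(n) - (n + 1) / 2) / rate_hz
  dur_s <- duration_us * 1e-6
  x <- gauss_component(t, centroid_hz, bandwidth_hz)
  if (is.finite(mid_band_gain_db))
    x <- x + db_to_amp(mid_band_gain_db) *
      gauss_component(t - dur_s / 8, mid_band_hz, mid_band_bandwidth_hz)
  if (is.finite(low_band_gain_db))
    x <- x + db_to_amp(low_band_gain_db) *
      gauss_component(t - dur_s / 4, low_band_hz, low_band_bandwidth_hz)
  x / max(abs(x))
}

#' Generate click-train onset times
#'
#' Onsets with independent uniform inter-click intervals in `ici_range_s`.
#' ICIs at or below 10 ms are the buzz/burst-pulse regime and are rejected.
#'
#' @param n number of clicks (>= 1)
#' @param ici_range_s `(min, max)` ICI in seconds with `min > 0.01`
#' @param seed optional integer seed (local RNG; the caller's stream is
#'   untouched)
#' @param start_s onset of the first click
#' @return increasing numeric vector of `n` onset times in seconds
#' @export
make_click_train <- function(n, ici_range_s = c(0.02, 0.15), seed = NULL,
                             start_s = 0) {
  stopifnot(n >= 1, length(ici_range_s) == 2)
  if (ici_range_s[1] <= 0.01)
    stop("minimum ICI must exceed 0.01 s (echolocation click trains)")
  if (ici_range_s[2] < ici_range_s[1]) stop("ici_range_s must be increasing")
  with_seed(seed, {
    icis <- if (n > 1) stats::runif(n - 1, ici_range_s[1], ici_range_s[2]) else numeric(0)
    start_s + cumsum(c(0, icis))
  })
}

#' Render a snapping-shrimp-like snap
#'
#' A very short (< 200 us) broadband transient with energy on both sides of
#' 48 kHz: a Gaussian-enveloped 48 kHz carrier whose spectral support spans
#' roughly 10-86 kHz. Deterministic; peak |amplitude| = 1. Snaps stand in for
#' impulsive soundscape interference that resembles dolphin clicks but does
#' not form trains.
#'
#' @param rate_hz sampling rate
#' @return numeric waveform (~120 us long)
#' @export
make_snap <- function(rate_hz) {
  make_click(centroid_hz = 48000, bandwidth_hz = 76000, duration_us = 120,
             rate_hz = rate_hz)
}

# Band-limited RMS of a noise vector via Parseval fraction.
band_rms <- function(x, rate_hz, lo_hz, hi_hz) {
  rms(x) * sqrt(band_energy_fraction(x, rate_hz, lo_hz, hi_hz))
}

#' Render a synthetic soundscape with ground truth
#'
#' Places echolocation click trains (train lengths 10-30 clicks, inter-train
#' gaps 0.4-1.5 s, ICIs within `ici_range_s`), draws each click's below-24 /
#' below-48 band flags (`below48 ~ Bernoulli(p_below48)`, then
#' `below24 | below48 ~ Bernoulli(p_below24 / p_below48)` so the marginal
#' probabilities and the nesting `below24 => below48` both hold), renders the
#' clicks over ambient noise, and adds Poisson-placed snaps kept at least
#' 5 ms away from any true click so detector specificity is identifiable.
#' Clicks are scaled to `snr_db` (peak) over the 15-90 kHz band RMS of the
#' noise; full scale is 1.0.
#'
#' @param config a [synth_config()]
#' @return list with `recording` (a [recording()]) and `truth`: a list with
#'   `clicks` (data.frame `begin_s, end_s, below24, below48, above48`,
#'   onset-sorted) and `snaps` (numeric onset times)
#' @export
render_soundscape <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, render_soundscape_impl(config))
}

render_soundscape_impl <- function(cfg) {
  rate <- cfg$rate_hz
  n <- round(cfg$duration_s * rate)
  noise_sigma <- 0.02
  x <- switch(cfg$noise_spectrum,
    none = numeric(n),
    white = stats::rnorm(n, sd = noise_sigma),
    pink = pink_noise(n, noise_sigma))

  click_len <- round(cfg$click_duration_us * 1e-6 * rate)
  target_n <- if (!is.null(cfg$n_clicks)) cfg$n_clicks
              else round(cfg$click_rate * cfg$duration_s)

  # click amplitude from the SNR convention (peak over 15-90 kHz noise RMS)
  amp <- if (cfg$noise_spectrum == "none") 0.5 else {
    nb_rms <- band_rms(x, rate, 15000, min(90000, rate / 2))
    db_to_amp(cfg$snr_db) * nb_rms
  }

  # onsets: trains of 10-30 clicks separated by 0.4-1.5 s gaps
  onsets <- numeric(0)
  t_cur <- stats::runif(1, 0.3, 0.8)
  margin <- (click_len + 1) / rate
  while (length(onsets) < target_n && t_cur < cfg$duration_s - margin - 0.1) {
    train_n <- min(sample(10:30, 1), target_n - length(onsets))
    tr <- make_click_train(train_n, cfg$ici_range_s, start_s = t_cur)
    tr <- tr[tr < cfg$duration_s - margin]
    onsets <- c(onsets, tr)
    t_cur <- max(tr) + stats::runif(1, 0.4, 1.5)
  }
  if (!is.null(cfg$n_clicks) && length(onsets) < cfg$n_clicks)
    warning("recording too short for the requested clicks: placed ",
            length(onsets), " of ", cfg$n_clicks)

  nc <- length(onsets)
  below48 <- stats::runif(nc) < cfg$p_below48
  p24_given_48 <- if (cfg$p_below48 > 0) cfg$p_below24 / cfg$p_below48 else 0
  below24 <- below48 & (stats::runif(nc) < p24_given_48)

  start_sample <- round(onsets * rate) + 1L
  for (i in seq_len(nc)) {
    w <- make_click(
      cfg$click_centroid_hz, cfg$click_bandwidth_hz, cfg$click_duration_us,
      rate,
      low_band_gain_db = if (below24[i]) 0 else -Inf,
      mid_band_gain_db = if (below48[i]) 0 else -Inf
    )
    idx <- start_sample[i]:(start_sample[i] + length(w) - 1L)
    x[idx] <- x[idx] + amp * w
  }

  # snaps: Poisson process, never within 5 ms of a true click
  snap_onsets <- numeric(0)
  if (cfg$snap_rate_per_s > 0) {
    n_snaps <- stats::rpois(1, cfg$snap_rate_per_s * cfg$duration_s)
    snap <- make_snap(rate)
    snap_len_s <- length(snap) / rate
    placed <- 0L; dropped <- 0L
    for (i in seq_len(n_snaps)) {
      ok <- FALSE
      for (try in 1:100) {
        cand <- stats::runif(1, 0, cfg$duration_s - snap_len_s - 1 / rate)
        if (nc == 0 || min(abs(cand - onsets)) > 0.005) { ok <- TRUE; break }
      }
      if (!ok) { dropped <- dropped + 1L; next }
      s0 <- round(cand * rate) + 1L
      idx <- s0:(s0 + length(snap) - 1L)
      x[idx] <- x[idx] + amp * snap
      snap_onsets <- c(snap_onsets, (s0 - 1L) / rate)
    }
    if (dropped > 0)
      warning(dropped, " snap(s) could not be placed clear of clicks and were dropped")
    snap_onsets <- sort(snap_onsets)
  }

  peak <- max(abs(x))
  if (peak > 0.999) x <- x * (0.999 / peak)

  ord <- order(start_sample)
  truth_clicks <- data.frame(
    begin_s = (start_sample[ord] - 1L) / rate,
    end_s = (start_sample[ord] - 1L + click_len) / rate,
    below24 = below24[ord], below48 = below48[ord],
    above48 = rep(TRUE, nc)
  )

  rec_id <- sprintf("synth_%s_seed%d", cfg$environment, cfg$seed)
  list(
    recording = recording(x, rate, recording_id = rec_id,
                          environment = cfg$environment,
                          group_id = paste0("grp_", cfg$environment)),
    truth = list(clicks = truth_clicks, snaps = snap_onsets)
  )
}

# 1/f-amplitude (pink) Gaussian noise by spectral shaping, scaled to the
# requested overall RMS.
pink_noise <- function(n, sigma) {
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  f <- c(1, seq_len(n - 1))           # avoid divide-by-zero at DC
  f <- pmin(f, n - f + 1)             # symmetric shaping
  X <- X / sqrt(f)
  x <- Re(stats::fft(X, inverse = TRUE) / n)
  x * sigma / rms(x)
}

#' Write a soundscape's ground truth as a Raven-style selection table
#'
#' Columns: `Selection`, `Begin Time (s)`, `End Time (s)`, `Low Freq (Hz)`,
#' `High Freq (Hz)`, `below24`, `below48`.
#'
#' @param truth the `truth` element returned by [render_soundscape()]
#' @param path output path
#' @param rate_hz sampling rate of the rendered recording (for the High Freq
#'   column)
#' @return `path`, invisibly
#' @export
write_truth_table <- function(truth, path, rate_hz = 192000) {
  sel <- truth$clicks
  sel$low_hz <- 0
  sel$high_hz <- rate_hz / 2
  write_selection_table(sel[, c("begin_s", "end_s", "low_hz", "high_hz",
                                "below24", "below48")], path)
}
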