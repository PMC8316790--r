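# Shared fixtures, built in code at test time.

# A pure-tone recording.
tone_recording <- function(freq_hz, duration_s = 1, rate_hz = 192000,
                           amplitude = 1) {
  t <- seq(0, duration_s - 1 / rate_hz, by = 1 / rate_hz)
  recording(amplitude * sin(2 * pi * freq_hz * t), rate_hz)
}

# Steady-state RMS level of a (filtered) recording in dB re a reference
# amplitude, measured away from the filter transient.
steady_level_db <- function(rec, ref_amplitude = 1 / sqrt(2)) {
  n <- length(rec$samples)
  x <- rec$samples[round(n * 0.3):round(n * 0.9)]
  20 * log10(sqrt(mean(x^2)) / ref_amplitude)
}

# A noiseless recording holding one click train with known onsets.
click_train_recording <- function(n_clicks = 20, ici_range = c(0.02, 0.06),
                                  rate_hz = 192000, seed = 1,
                                  amplitude = 0.5, pad_s = 0.3) {
  onsets <- make_click_train(n_clicks, ici_range, seed = seed, start_s = pad_s)
  w <- make_click(70000, 36000, 400, rate_hz,
                  low_band_gain_db = 0, mid_band_gain_db = 0)
  dur <- max(onsets) + pad_s + 0.1
  x <- numeric(round(dur * rate_hz))
  s0 <- round(onsets * rate_hz) + 1
  amplitude <- rep_len(amplitude, n_clicks)
  for (i in seq_along(s0)) {
    s <- s0[i]
    x[s:(s + length(w) - 1)] <- x[s:(s + length(w) - 1)] + amplitude[i] * w
  }
  list(recording = recording(x, rate_hz),
       truth = data.frame(begin_s = onsets,
                          end_s = onsets + length(w) / rate_hz))
}

# Random detection intervals for oracle comparisons.
random_detections <- function(n, t_max = 60) {
  b <- sort(stats::runif(n, 0, t_max))
  data.frame(begin_s = b, end_s = b + stats::runif(n, 1e-4, 0.5))
}

# Simulate paired proportion records from the GLMM's own generative model:
# logit p = intercept + effect * (freq == "24") + recording intercept +
# sample intercept.
simulate_proportions <- function(n_recordings = 10, samples_per_rec = 20,
                                 den = 50, intercept = 2, effect = -2,
                                 sd_recording = 0.5, sd_sample = 0.2) {
  n_samples <- n_recordings * samples_per_rec
  rec <- factor(rep(seq_len(n_recordings), each = samples_per_rec * 2))
  samp <- factor(rep(seq_len(n_samples), each = 2))
  freq <- factor(rep(c("24", "48"), n_samples), levels = c("24", "48"))
  u_rec <- stats::rnorm(n_recordings, 0, sd_recording)
  u_samp <- stats::rnorm(n_samples, 0, sd_sample)
  eta <- intercept + (freq == "24") * effect +
    u_rec[as.integer(rec)] + u_samp[as.integer(samp)]
  data.frame(
    sample_id = paste0("s", samp), recording_id = paste0("r", rec),
    freq = freq, numerator = stats::rbinom(length(eta), den, stats::plogis(eta)),
    denominator = den, stringsAsFactors = FALSE
  )
}
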