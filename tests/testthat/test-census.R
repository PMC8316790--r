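rate <- 192000

# A recording holding one synthetic click over white noise, for controlled
# band-occurrence checks.
one_click_recording <- function(click, snr_db = 25, seed = 1, dur_s = 1.5) {
  set.seed(seed)
  x <- rnorm(dur_s * rate, sd = 0.02)
  nrms <- sqrt(mean(x^2)) * sqrt(band_energy_fraction(x, rate, 15000, 90000))
  amp <- 10^(snr_db / 20) * nrms
  s0 <- round(0.7 * rate)
  x[s0:(s0 + length(click) - 1)] <- x[s0:(s0 + length(click) - 1)] + amp * click
  list(rec = recording(x, rate),
       begin_s = (s0 - 1) / rate, end_s = (s0 - 1 + length(click)) / rate)
}

test_that("band_occurrence judges constructed clicks correctly", {
  # click with a full-gain low band: occurs below 24 kHz
  low <- one_click_recording(make_click(70000, 36000, 400, rate,
                                        low_band_gain_db = 0,
                                        mid_band_gain_db = 0), seed = 2)
  spec <- spectrogram(low$rec)
  expect_true(band_occurrence(spec, low$begin_s, low$end_s, c(5000, 24000)))

  # click with energy only at 30-60 kHz: false below 24, true below 48
  mid <- one_click_recording(make_click(45000, 30000, 400, rate), seed = 3)
  spec_mid <- spectrogram(mid$rec)
  expect_false(band_occurrence(spec_mid, mid$begin_s, mid$end_s, c(5000, 24000)))
  expect_true(band_occurrence(spec_mid, mid$begin_s, mid$end_s, c(5000, 48000)))

  # silence window: false for any band
  expect_false(band_occurrence(spec, 0.2, 0.21, c(5000, 24000)))
  expect_false(band_occurrence(spec, 0.2, 0.21, c(5000, 48000)))

  # empty band errors
  expect_error(band_occurrence(spec, low$begin_s, low$end_s, c(100, 200)),
               "no frequency bins")
})

test_that("census flags agree with generator flags at SNR >= 20", {
  sc <- render_soundscape(synth_config(duration_s = 20, click_rate = 15,
                                       snr_db = 20, environment = "open",
                                       p_below24 = 0.6, p_below48 = 0.9,
                                       seed = 13))
  spec <- spectrogram(sc$recording)
  cc <- census_clicks(sc$truth$clicks, spec)
  tr <- sc$truth$clicks
  expect_gte(mean(cc$below24 == tr$below24), 0.95)
  expect_gte(mean(cc$below48 == tr$below48), 0.95)
  # the census respects the nesting invariant by construction
  expect_true(all(cc$below48[cc$below24]))
  # determinism given the spectrogram
  cc2 <- census_clicks(sc$truth$clicks, spec)
  expect_identical(cc, cc2)
})

test_that("census agreement does not degrade as SNR increases", {
  agree <- vapply(c(15, 25), function(snr) {
    sc <- render_soundscape(synth_config(duration_s = 12, click_rate = 15,
                                         snr_db = snr, environment = "open",
                                         p_below24 = 0.6, p_below48 = 0.9,
                                         seed = 31))
    spec <- spectrogram(sc$recording)
    cc <- census_clicks(sc$truth$clicks, spec)
    (mean(cc$below24 == sc$truth$clicks$below24) +
       mean(cc$below48 == sc$truth$clicks$below48)) / 2
  }, numeric(1))
  expect_gte(agree[2], agree[1] - 0.02)  # small slack for sampling noise
})

test_that("echolocation_filter removes buzz-regime clicks only", {
  # ICIs all 50 ms: unchanged
  cl <- data.frame(begin_s = seq(0, 0.5, by = 0.05))
  cl$end_s <- cl$begin_s + 4e-4
  expect_identical(echolocation_filter(cl), cl)

  # a 5 ms pair inside a 50 ms train: exactly that pair removed
  on <- c(0, 0.05, 0.1, 0.105, 0.155, 0.205)
  cl2 <- data.frame(begin_s = on, end_s = on + 4e-4)
  kept <- echolocation_filter(cl2)
  expect_equal(kept$begin_s, c(0, 0.05, 0.155, 0.205))

  # single click kept
  single <- data.frame(begin_s = 1, end_s = 1.0004)
  expect_identical(echolocation_filter(single), single)
})

test_that("census_sample applies the paired counting rule", {
  unit <- data.frame(recording_id = "r", index = 1, start_s = 0, end_s = 60,
                     duration_s = 60)
  mk <- function(n, b24, b48) {
    if (n == 0) return(NULL)
    data.frame(begin_s = seq_len(n) * 0.1, end_s = seq_len(n) * 0.1 + 4e-4,
               below24 = b24, below48 = b48)
  }
  # 10 clicks all below 24 -> (10, 10, 10)
  all24 <- mk(10, TRUE, TRUE)
  cnt <- census_sample(unit, all24)
  expect_equal(c(cnt$n_total, cnt$n_below24, cnt$n_below48), c(10, 10, 10))

  # 3 below24, 2 between 24 and 48 only, 1 above 48 only -> (6, 3, 5)
  mixed <- rbind(mk(3, TRUE, TRUE), mk(2, FALSE, TRUE), mk(1, FALSE, FALSE))
  mixed$begin_s <- seq_len(6) * 0.1; mixed$end_s <- mixed$begin_s + 4e-4
  cnt2 <- census_sample(unit, mixed)
  expect_equal(c(cnt2$n_total, cnt2$n_below24, cnt2$n_below48), c(6, 3, 5))
  # oracle: independent enumeration over the flags
  expect_equal(cnt2$n_below48, sum(mixed$below24 | (mixed$below48 & !mixed$below24)))

  # zero clicks -> (0, 0, 0)
  cnt3 <- census_sample(unit, mk(3, TRUE, TRUE)[0, ])
  expect_equal(c(cnt3$n_total, cnt3$n_below24, cnt3$n_below48), c(0, 0, 0))

  # nesting invariant on many random flag draws
  set.seed(8)
  for (i in 1:20) {
    n <- sample(1:40, 1)
    b48 <- runif(n) < 0.8
    b24 <- b48 & runif(n) < 0.6
    cl <- data.frame(begin_s = cumsum(runif(n, 0.02, 0.15)))
    cl$end_s <- cl$begin_s + 4e-4; cl$below24 <- b24; cl$below48 <- b48
    cnt <- census_sample(unit, cl)
    expect_lte(cnt$n_below24, cnt$n_below48)
    expect_lte(cnt$n_below48, cnt$n_total)
  }
})

test_that("census_to_proportions pairs thresholds and excludes empty samples", {
  counts <- data.frame(recording_id = c("r", "r"), index = 1:2,
                       n_total = c(100, 0), n_below24 = c(95, 0),
                       n_below48 = c(99, 0))
  expect_message(pr <- census_to_proportions(counts), "excluding 1")
  expect_equal(nrow(pr), 2)
  expect_equal(pr$numerator[pr$freq == "24"], 95)
  expect_equal(pr$numerator[pr$freq == "48"], 99)
  expect_equal(pr$denominator, c(100, 100))

  empty <- counts[2, , drop = FALSE]
  expect_message(pr0 <- census_to_proportions(empty))
  expect_equal(nrow(pr0), 0)
})

test_that("census totals match an independent per-sample tally", {
  sc <- render_soundscape(synth_config(duration_s = 10, click_rate = 12,
                                       seed = 17, environment = "lagoon"))
  tr <- sc$truth$clicks
  units <- segment_samples(sc$recording, unit_s = 2)
  counts <- do.call(rbind, lapply(seq_len(nrow(units)), function(u)
    census_sample(units[u, , drop = FALSE], tr)))
  # independent tally: bin clicks by floor(begin / 2)
  tab <- table(factor(floor(tr$begin_s / 2), levels = 0:(nrow(units) - 1)))
  expect_equal(counts$n_total, as.integer(tab))
  expect_equal(sum(counts$n_total), nrow(tr))
  expect_equal(sum(counts$n_below24), sum(tr$below24))
})
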