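rate <- 192000

test_that("envelope tracks amplitude", {
  # constant-amplitude tone -> near-constant envelope away from the edges
  x <- sin(2 * pi * 10000 * (0:(rate / 4)) / rate)
  env <- envelope(x, smooth_ms = 0.5, rate_hz = rate)
  core <- env[round(length(env) * 0.1):round(length(env) * 0.9)]
  expect_lt((max(core) - min(core)) / mean(core), 0.05)

  # silence -> zeros
  expect_equal(envelope(rep(0, 1000), 0.5, rate), rep(0, 1000))

  # isolated click -> one envelope peak at the click time
  fix <- click_train_recording(n_clicks = 1, seed = 2)
  env2 <- envelope(fix$recording, smooth_ms = 0.5)
  expect_lt(abs(which.max(env2) / rate - fix$truth$begin_s[1]), 1e-3)
})

test_that("detect finds noiseless clicks at millisecond accuracy", {
  fix <- click_train_recording(n_clicks = 20, seed = 4)
  det <- detect(fix$recording, detector_params(threshold_pct = 10))
  expect_equal(nrow(det), 20)
  expect_true(all(abs(det$begin_s - fix$truth$begin_s) < 1e-3))
  expect_true(all(diff(det$begin_s) > 0))
  expect_true(all(det$begin_s[-1] >= det$end_s[-nrow(det)]))

  # threshold 100%: only the maximum crosses -> at most one detection
  det100 <- detect(fix$recording, detector_params(threshold_pct = 100))
  expect_lte(nrow(det100), 1)

  # all-zero recording -> empty result
  expect_equal(nrow(detect(recording(rep(0, 5000), rate))), 0)
})

test_that("merge gap joins close crossings into one detection", {
  w <- make_click(70000, 36000, 400, rate)
  x <- numeric(rate %/% 10)
  s1 <- 5000
  s2 <- s1 + length(w) + round(0.0005 * rate)  # 0.5 ms gap
  x[s1:(s1 + length(w) - 1)] <- w
  x[s2:(s2 + length(w) - 1)] <- w
  rec <- recording(x, rate)
  det_merged <- detect(rec, detector_params(threshold_pct = 10, merge_gap_ms = 1))
  expect_equal(nrow(det_merged), 1)
  det_split <- detect(rec, detector_params(threshold_pct = 10, merge_gap_ms = 0.2,
                                           min_dur_ms = 0.05))
  expect_equal(nrow(det_split), 2)
})

test_that("detection count is monotone non-increasing in threshold", {
  set.seed(6)
  fix <- click_train_recording(n_clicks = 30, seed = 6,
                               amplitude = runif(30, 0.1, 0.9))
  counts <- vapply(c(10, 15, 25, 35, 50, 80, 95), function(th)
    nrow(detect(fix$recording, detector_params(threshold_pct = th))),
    numeric(1))
  expect_equal(counts[1], 30)
  expect_true(all(diff(counts) <= 0))
})

test_that("score_detector equals an all-pairs overlap oracle", {
  # exact cases
  ref <- data.frame(begin_s = c(1, 2, 3), end_s = c(1.1, 2.1, 3.1))
  expect_equal(score_detector(ref, ref), list(sensitivity = 1, specificity = 1))
  half <- ref[1:2, ]; half$begin_s <- half$begin_s + 0.05
  sc <- score_detector(half[1, , drop = FALSE], ref[1:2, ])
  expect_equal(sc$sensitivity, 0.5); expect_equal(sc$specificity, 1)
  spurious <- data.frame(begin_s = c(10, 20), end_s = c(10.1, 20.1))
  expect_equal(score_detector(spurious, ref), list(sensitivity = 0, specificity = 0))
  expect_equal(score_detector(ref[0, ], ref), list(sensitivity = 0, specificity = 0))
  expect_error(score_detector(ref, ref[0, ]), "empty reference")

  # random instances vs brute-force O(n^2) loop
  set.seed(10)
  for (i in 1:20) {
    det <- random_detections(sample(1:15, 1))
    refr <- random_detections(sample(1:15, 1))
    got <- score_detector(det, refr)
    hit_ref <- vapply(seq_len(nrow(refr)), function(j)
      any(det$begin_s < refr$end_s[j] & det$end_s > refr$begin_s[j]), logical(1))
    hit_det <- vapply(seq_len(nrow(det)), function(j)
      any(refr$begin_s < det$end_s[j] & refr$end_s > det$begin_s[j]), logical(1))
    expect_equal(got$sensitivity, mean(hit_ref))
    expect_equal(got$specificity, mean(hit_det))
  }
})

test_that("optimize_params maximises mean sensitivity + specificity", {
  fix <- click_train_recording(n_clicks = 15, seed = 5)
  sub <- list(list(recording = fix$recording, reference = fix$truth))

  # single-point grid returns that point
  g1 <- data.frame(threshold_pct = 20, smooth_ms = 0.5, min_dur_ms = 0.05,
                   max_dur_ms = 25, merge_gap_ms = 1)
  p1 <- optimize_params(sub, g1)
  expect_equal(p1$threshold_pct, 20)

  # grid containing workable parameters scores (1, 1) on a noiseless fixture
  best <- optimize_params(sub, default_detector_grid())
  expect_equal(attr(best, "mean_score"), 2)
  sc <- score_detector(detect(fix$recording, best), fix$truth)
  expect_equal(sc$sensitivity, 1)
  expect_equal(sc$specificity, 1)

  # optimizer's best equals an independent exhaustive loop
  grid <- expand.grid(threshold_pct = c(10, 30, 60), smooth_ms = c(0.1, 0.5),
                      min_dur_ms = 0.05, max_dur_ms = 25, merge_gap_ms = 1)
  got <- optimize_params(sub, grid)
  brute <- max(vapply(seq_len(nrow(grid)), function(i) {
    p <- detector_params(grid$threshold_pct[i], grid$smooth_ms[i],
                         grid$min_dur_ms[i], grid$max_dur_ms[i],
                         grid$merge_gap_ms[i])
    s <- score_detector(detect(fix$recording, p), fix$truth)
    s$sensitivity + s$specificity
  }, numeric(1)))
  expect_equal(attr(got, "mean_score"), brute)

  expect_error(optimize_params(sub, g1[0, ]), "empty parameter grid")
  expect_error(optimize_params(list(list(recording = fix$recording,
                                         reference = fix$truth[0, ])), g1),
               "empty reference")
})

test_that("interval_filter keeps only train-embedded detections", {
  mk <- function(on) data.frame(begin_s = on, end_s = on + 4e-4,
                                peak_level = rep(1, length(on)))
  # two detections 0.1 s apart: both kept
  expect_equal(nrow(interval_filter(mk(c(1, 1.1)))), 2)
  # a lone detection is removed (echolocation clicks are not isolated)
  expect_equal(nrow(interval_filter(mk(5))), 0)
  # gaps 0.1, 0.3, 0.1: every detection has one qualifying neighbour
  expect_equal(nrow(interval_filter(mk(c(0, 0.1, 0.4, 0.5)))), 4)
  # gaps 0.3, 0.3: all removed
  expect_equal(nrow(interval_filter(mk(c(0, 0.3, 0.6)))), 0)
  # empty input passes through
  expect_equal(nrow(interval_filter(mk(numeric(0)))), 0)

  # single-pass semantics vs a brute-force neighbour scan, random sets
  set.seed(11)
  for (i in 1:25) {
    det <- random_detections(sample(1:30, 1), t_max = 10)
    got <- interval_filter(det)
    gaps <- diff(det$begin_s)
    keep <- c(gaps <= 0.2, FALSE) | c(FALSE, gaps <= 0.2)
    if (nrow(det) == 1) keep <- FALSE
    expect_equal(got$begin_s, det$begin_s[keep])
  }
})
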