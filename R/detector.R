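# Approach 2, stage 1: envelope-threshold automatic click detection, grid
# optimisation of detector parameters against annotated subsamples, and the
# 0.2 s inter-detection interval filter that strips isolated (snap-like)
# detections.

#' Detector parameters
#'
#' @param threshold_pct detection threshold as a percentage of the recording's
#'   maximum envelope (relative threshold: each recording is implicitly
#'   normalised to its own loudest event)
#' @param smooth_ms envelope smoothing (moving-average) window in ms
#' @param min_dur_ms,max_dur_ms detection duration gates in ms
#' @param merge_gap_ms threshold crossings closer than this merge into one
#'   detection
#' @param band_hz optional `(lo, hi)` analysis band applied before the
#'   envelope (`NULL` = broadband)
#' @return an object of class `"detector_params"`
#' @export
detector_params <- function(threshold_pct = 10, smooth_ms = 0.5,
                            min_dur_ms = 0.05, max_dur_ms = 25,
                            merge_gap_ms = 1, band_hz = NULL) {
  stopifnot(threshold_pct > 0, threshold_pct <= 100,
            min_dur_ms < max_dur_ms, min_dur_ms > 0,
            smooth_ms > 0, merge_gap_ms > 0)
  structure(list(threshold_pct = threshold_pct, smooth_ms = smooth_ms,
                 min_dur_ms = min_dur_ms, max_dur_ms = max_dur_ms,
                 merge_gap_ms = merge_gap_ms, band_hz = band_hz),
            class = "detector_params")
}

#' Amplitude envelope of a recording
#'
#' Magnitude of the analytic (Hilbert) signal smoothed by a centred moving
#' average of `smooth_ms` milliseconds.
#'
#' @param rec a `pam_recording` or numeric vector
#' @param smooth_ms smoothing window in ms
#' @param rate_hz required when `rec` is a bare vector
#' @return non-negative numeric vector, same length as the input
#' @export
envelope <- function(rec, smooth_ms = 0.5, rate_hz = NULL) {
  if (inherits(rec, "pam_recording")) {
    x <- rec$samples; rate_hz <- rec$rate_hz
  } else {
    x <- as.numeric(rec)
    if (is.null(rate_hz)) stop("rate_hz is required for a bare vector")
  }
  env <- analytic_magnitude(x)
  moving_average(env, max(1L, round(smooth_ms * 1e-3 * rate_hz)))
}

# Shared core: threshold an envelope, merge close crossings, gate durations.
detect_from_envelope <- function(env, rate_hz, params) {
  peak <- max(env)
  if (peak <= 0) return(empty_detections())
  thr <- peak * params$threshold_pct / 100
  above <- env >= thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  if (nrow(runs) == 0) return(empty_detections())
  # merge runs separated by gaps shorter than merge_gap_ms
  gap_n <- params$merge_gap_ms * 1e-3 * rate_hz
  if (nrow(runs) > 1) {
    gaps <- runs[-1, 1] - runs[-nrow(runs), 2] - 1
    new_group <- c(TRUE, gaps >= gap_n)
    grp <- cumsum(new_group)
    runs <- cbind(tapply(runs[, 1], grp, min), tapply(runs[, 2], grp, max))
  }
  dur_ms <- (runs[, 2] - runs[, 1] + 1) / rate_hz * 1e3
  keep <- dur_ms >= params$min_dur_ms & dur_ms <= params$max_dur_ms
  runs <- runs[keep, , drop = FALSE]
  if (nrow(runs) == 0) return(empty_detections())
  peaks <- vapply(seq_len(nrow(runs)),
                  function(i) max(env[runs[i, 1]:runs[i, 2]]), numeric(1))
  data.frame(begin_s = (runs[, 1] - 1) / rate_hz,
             end_s = runs[, 2] / rate_hz,
             peak_level = peaks, row.names = NULL)
}

empty_detections <- function() {
  data.frame(begin_s = numeric(0), end_s = numeric(0), peak_level = numeric(0))
}

#' Envelope-threshold click detection
#'
#' Detections are maximal runs where the smoothed envelope is at least
#' `threshold_pct`% of its maximum, merged across gaps shorter than
#' `merge_gap_ms`, then kept if their duration lies in
#' `[min_dur_ms, max_dur_ms]`. Output is time-sorted and non-overlapping.
#'
#' @param rec a `pam_recording`
#' @param params a [detector_params()]
#' @return data.frame with `begin_s`, `end_s` (half-open), `peak_level`
#' @export
detect <- function(rec, params = detector_params()) {
  stopifnot(inherits(rec, "pam_recording"), inherits(params, "detector_params"))
  x <- rec
  if (!is.null(params$band_hz)) {
    x <- butterworth_highpass(x, params$band_hz[1])
    if (params$band_hz[2] < rec$rate_hz / 2)
      x <- antialias_lowpass(x, params$band_hz[2])
  }
  env <- envelope(x, params$smooth_ms)
  detect_from_envelope(env, rec$rate_hz, params)
}

#' Score detections against a reference selection table
#'
#' A reference signal is "hit" when any detection overlaps it (half-open
#' interval overlap). Sensitivity is the fraction of reference signals hit;
#' specificity — operationalised as precision, since true negatives are
#' undefined for point events — is the fraction of detections overlapping any
#' reference.
#'
#' @param detections data.frame with `begin_s`, `end_s`
#' @param reference data.frame with `begin_s`, `end_s`; must be non-empty
#' @return list with `sensitivity` and `specificity`, both in \[0, 1\]
#'   (both 0 when there are no detections)
#' @export
score_detector <- function(detections, reference) {
  if (nrow(reference) == 0) stop("cannot score against an empty reference")
  if (nrow(detections) == 0) return(list(sensitivity = 0, specificity = 0))
  overlaps <- outer(detections$begin_s, reference$end_s, `<`) &
    outer(detections$end_s, reference$begin_s, `>`)
  list(sensitivity = mean(colSums(overlaps) > 0),
       specificity = mean(rowSums(overlaps) > 0))
}

#' Default detector parameter grid
#'
#' The grid searched by [optimize_params()]: threshold 5-40% in 5% steps,
#' smoothing 0.1/0.5/1 ms, minimum duration 0.05/0.1 ms, maximum duration
#' 5/25 ms, merge gap 1/2 ms (192 combinations).
#'
#' @return data.frame, one row per grid point, in lexicographic order
#' @export
default_detector_grid <- function() {
  expand.grid(threshold_pct = seq(5, 40, by = 5),
              smooth_ms = c(0.1, 0.5, 1),
              min_dur_ms = c(0.05, 0.1),
              max_dur_ms = c(5, 25),
              merge_gap_ms = c(1, 2),
              KEEP.OUT.ATTRS = FALSE)
}

#' Optimise detector parameters on annotated subsamples
#'
#' Runs the detector at every grid point over every labelled subsample and
#' returns the point with the highest mean (sensitivity + specificity),
#' breaking ties by grid order (first wins). The per-point, per-subsample
#' scores are attached as attribute `"report"`.
#'
#' @param subsamples list of `list(recording = <pam_recording>,
#'   reference = <selection data.frame>)`; each reference must be non-empty
#' @param grid data.frame of grid points (see [default_detector_grid()])
#' @return the best [detector_params()], with a `"report"` attribute
#' @export
optimize_params <- function(subsamples, grid = default_detector_grid()) {
  stopifnot(length(subsamples) >= 1)
  if (nrow(grid) == 0) stop("empty parameter grid")
  for (s in subsamples)
    if (nrow(s$reference) == 0) stop("subsample with empty reference cannot be scored")
  report <- vector("list", nrow(grid) * length(subsamples))
  scores <- matrix(NA_real_, nrow = nrow(grid), ncol = length(subsamples))
  for (j in seq_along(subsamples)) {
    rec <- subsamples[[j]]$recording
    ref <- subsamples[[j]]$reference
    raw_env <- analytic_magnitude(rec$samples)
    env_cache <- new.env()
    for (i in seq_len(nrow(grid))) {
      g <- grid[i, ]
      key <- as.character(g$smooth_ms)
      if (is.null(env_cache[[key]]))
        env_cache[[key]] <- moving_average(
          raw_env, max(1L, round(g$smooth_ms * 1e-3 * rec$rate_hz)))
      p <- detector_params(g$threshold_pct, g$smooth_ms, g$min_dur_ms,
                           g$max_dur_ms, g$merge_gap_ms)
      det <- detect_from_envelope(env_cache[[key]], rec$rate_hz, p)
      sc <- score_detector(det, ref)
      scores[i, j] <- sc$sensitivity + sc$specificity
      report[[(i - 1) * length(subsamples) + j]] <- data.frame(
        grid_point = i, subsample = j, g,
        sensitivity = sc$sensitivity, specificity = sc$specificity)
    }
  }
  mean_scores <- rowMeans(scores)
  best <- which.max(mean_scores)   # which.max takes the first maximum
  g <- grid[best, ]
  out <- detector_params(g$threshold_pct, g$smooth_ms, g$min_dur_ms,
                         g$max_dur_ms, g$merge_gap_ms)
  attr(out, "report") <- do.call(rbind, report)
  attr(out, "mean_score") <- mean_scores[best]
  out
}

#' Inter-detection interval filter
#'
#' Echolocation clicks occur in trains, not isolated: a detection is kept iff
#' its onset-to-onset gap to the previous OR next detection is at most
#' `max_gap_s`. Single-pass on the original gaps (the rule is a one-shot
#' exclusion, not a fixpoint iteration); a lone detection is removed.
#'
#' @param detections time-sorted data.frame with `begin_s`
#' @param max_gap_s maximum qualifying gap (0.2 s)
#' @return the filtered data.frame
#' @export
interval_filter <- function(detections, max_gap_s = 0.2) {
  n <- nrow(detections)
  if (n == 0) return(detections)
  if (n == 1) return(detections[0, , drop = FALSE])
  on <- detections$begin_s
  if (is.unsorted(on)) stop("detections must be time-sorted")
  gap_prev <- c(Inf, diff(on))
  gap_next <- c(diff(on), Inf)
  out <- detections[gap_prev <= max_gap_s | gap_next <= max_gap_s, , drop = FALSE]
  rownames(out) <- NULL
  out
}
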