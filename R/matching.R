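# Approach 2, stage 2: buffer expansion of original-rate detections,
# 1-second presence binning per sample unit, and cross-rate bin matching.
# The matched proportions are the response of the second mixed model.

#' Expand detections by their own duration
#'
#' Each detection `(b, e)` becomes `(max(0, b - d), e + d)` with `d = e - b`.
#' Applied only to original-rate (96 kHz Nyquist) detections before matching,
#' because detections in downsampled recordings tend to be longer; the buffer
#' guarantees the same signal lands in the same 1-s bin at every rate.
#' Overlaps between expanded intervals are permitted.
#'
#' @param detections data.frame with `begin_s`, `end_s`
#' @return data.frame with expanded `begin_s`, `end_s`
#' @export
buffer_expand <- function(detections) {
  d <- detections$end_s - detections$begin_s
  out <- detections
  out$begin_s <- pmax(0, detections$begin_s - d)
  out$end_s <- detections$end_s + d
  out
}

#' Binarize events into 1-second presence bins
#'
#' Bins tile the sample unit from its start; the last bin may be partial (a
#' detection in a 0.4 s remainder still counts). Bin `b` (0-based) is present
#' iff any event interval intersects `[start + b, start + b + 1)`; zero-length
#' events count as points.
#'
#' @param events data.frame with `begin_s`, `end_s` (recording-relative)
#' @param sample_unit one row of [segment_samples()]
#' @return an object of class `"bin_series"`: list with `sample_id`,
#'   `presence` (logical, `ceiling(duration)` bins), `start_s`
#' @export
binarize <- function(events, sample_unit) {
  stopifnot(nrow(sample_unit) == 1)
  start <- sample_unit$start_s
  n_bins <- ceiling(sample_unit$duration_s - 1e-9)
  presence <- logical(n_bins)
  if (nrow(events) > 0) {
    for (b in seq_len(n_bins)) {
      lo <- start + (b - 1); hi <- start + b
      hit <- (pmin(events$end_s, hi) > pmax(events$begin_s, lo)) |
        (events$begin_s == events$end_s &
           events$begin_s >= lo & events$begin_s < hi)
      presence[b] <- any(hit)
    }
  }
  structure(list(sample_id = paste0(sample_unit$recording_id, "#",
                                    sample_unit$index),
                 presence = presence, start_s = start),
            class = "bin_series")
}

#' Match presence bins across sampling rates
#'
#' The denominator is the number of bins with signal presence in the original
#' (buffer-expanded) series; the numerator is how many of those same bins are
#' also present in the downsampled series. Bins present only in the
#' downsampled series (possible false positives at the reduced rate) are
#' counted but not used.
#'
#' @param original a [binarize()] series from original-rate detections
#'   (buffer-expanded)
#' @param downsampled a [binarize()] series from one downsampled rate
#' @return data.frame row: `sample_id, numerator, denominator, n_down_only`
#' @export
match_bins <- function(original, downsampled) {
  stopifnot(inherits(original, "bin_series"), inherits(downsampled, "bin_series"))
  if (length(original$presence) != length(downsampled$presence))
    stop("bin series have different bin counts (", length(original$presence),
         " vs ", length(downsampled$presence), ")")
  if (!identical(original$sample_id, downsampled$sample_id))
    stop("bin series belong to different sample units")
  data.frame(
    sample_id = original$sample_id,
    numerator = sum(original$presence & downsampled$presence),
    denominator = sum(original$presence),
    n_down_only = sum(downsampled$presence & !original$presence),
    stringsAsFactors = FALSE
  )
}

#' Full detection-matching pipeline for one recording
#'
#' Detects clicks at the original rate and at the requested downsampled
#' rates, applies the 0.2 s interval filter at every rate, buffer-expands the
#' original-rate detections, bins everything per 1-min sample unit, and
#' matches bins. Frequency labels follow the Nyquist convention: a 96 kHz
#' sampling rate is labelled "48", 48 kHz is labelled "24", and the original
#' 192 kHz recording is labelled "96".
#'
#' @param rec a 192 kHz `pam_recording`
#' @param params a [detector_params()] (optimised per rate in the full
#'   experiment; a single set is accepted here and reused across rates)
#' @param target_rates_hz downsampled rates to evaluate
#' @param max_gap_s interval-filter gap
#' @param unit_s sample-unit length in seconds (60 for the standard 1-min
#'   samples; shorter units are useful for compact simulation studies)
#' @return data.frame: one row per sample unit x frequency label with
#'   `numerator`, `denominator`, `n_down_only`, `freq`, plus recording
#'   metadata. Sample units with zero original-rate presence bins are
#'   excluded.
#' @export
match_recording <- function(rec, params = detector_params(),
                            target_rates_hz = c(96000, 48000),
                            max_gap_s = 0.2, unit_s = 60) {
  stopifnot(inherits(rec, "pam_recording"))
  units <- segment_samples(rec, unit_s = unit_s)
  det_orig <- interval_filter(detect(rec, params), max_gap_s)
  det_orig_exp <- buffer_expand(det_orig)
  rows <- list()
  for (rate in target_rates_hz) {
    down <- downsample_chain(rec, rate)
    det_down <- interval_filter(detect(down, params), max_gap_s)
    freq_label <- as.character(rate / 2000)
    for (u in seq_len(nrow(units))) {
      unit <- units[u, , drop = FALSE]
      orig_bins <- binarize(det_orig_exp, unit)
      down_bins <- binarize(det_down, unit)
      m <- match_bins(orig_bins, down_bins)
      if (m$denominator == 0) next
      m$freq <- freq_label
      m$recording_id <- rec$recording_id
      m$environment <- rec$environment
      m$group_id <- rec$group_id
      rows[[length(rows) + 1]] <- m
    }
  }
  if (length(rows) == 0)
    return(data.frame(sample_id = character(0), numerator = integer(0),
                      denominator = integer(0), n_down_only = integer(0),
                      freq = character(0), recording_id = character(0),
                      environment = character(0), group_id = character(0)))
  out <- do.call(rbind, rows)
  out$freq <- factor(out$freq, levels = c("24", "48"))
  rownames(out) <- NULL
  out
}
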