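# Approach 1: an automated surrogate for the visual spectrogram census.
# Each annotated click is judged for spectral occurrence below the 24 and
# 48 kHz thresholds against a local per-band noise floor, then tallied into
# paired per-sample proportions (the response of the first mixed model).

#' Judge a click's spectral occurrence in a frequency band
#'
#' The automated stand-in for the analyst's eye: within each frame covering
#' the click, every band bin's level is compared with its local noise floor —
#' the median level of frames within `context_s` of the click, excluding
#' frames that overlap the click itself. The click "occurs" in the band when
#' some single frame holds at least `min_run_bins` *consecutive* bins
#' exceeding their floors by `noise_margin_db` or more: what an analyst sees
#' is a vertical stripe spanning a stretch of the band in one time column,
#' whereas noise exceedances are scattered single bins. `min_run_bins = 1`
#' reduces to the plain any-bin-exceeds criterion, which false-alarms on the
#' extreme order statistic of the noise and is not recommended.
#'
#' @param spec a [spectrogram()] of the recording
#' @param begin_s,end_s click window in seconds (must lie within the
#'   spectrogram's time span)
#' @param band_hz numeric `(lo, hi)` band edges in Hz
#' @param noise_margin_db detectability margin in dB (default 6)
#' @param context_s half-width of the noise-floor context around the click
#' @param min_run_bins minimum length of the run of consecutive exceeding
#'   bins (default 5, about 1.9 kHz at 192 kHz / 512-point frames)
#' @return logical
#' @export
band_occurrence <- function(spec, begin_s, end_s, band_hz,
                            noise_margin_db = 6, context_s = 0.5,
                            min_run_bins = 5) {
  stopifnot(inherits(spec, "pam_spectrogram"), length(band_hz) == 2,
            end_s > begin_s)
  bins <- which(spec$freq_hz >= band_hz[1] & spec$freq_hz <= band_hz[2])
  if (length(bins) == 0)
    stop("band ", band_hz[1], "-", band_hz[2], " Hz contains no frequency bins")
  half_frame <- spec$nfft / (2 * spec$rate_hz)
  in_window <- spec$time_s >= begin_s - half_frame & spec$time_s <= end_s + half_frame
  if (!any(in_window))
    stop("click window lies outside the spectrogram's time span")
  centre <- (begin_s + end_s) / 2
  in_context <- abs(spec$time_s - centre) <= context_s & !in_window
  if (!any(in_context))
    stop("no context frames available for the noise floor")
  level_db <- function(m) 20 * log10(pmax(m, 1e-12))
  floor_db <- level_db(apply(spec$mag[bins, in_context, drop = FALSE], 1, stats::median))
  win_levels <- level_db(spec$mag[bins, in_window, drop = FALSE])
  for (j in seq_len(ncol(win_levels))) {
    exceeds <- win_levels[, j] >= floor_db + noise_margin_db
    if (min_run_bins <= 1) {
      if (any(exceeds)) return(TRUE)
    } else {
      r <- rle(exceeds)
      if (any(r$values & r$lengths >= min_run_bins)) return(TRUE)
    }
  }
  FALSE
}

#' Classify annotated clicks below the 24 and 48 kHz thresholds
#'
#' Runs [band_occurrence()] for each click over the 5-24 kHz and 5-48 kHz
#' bands (the lower edge of 5 kHz keeps low-frequency ambient noise out of
#' the judgement, as a visual analyst implicitly does). Because the 5-48 kHz
#' band contains the 5-24 kHz band, the counting rule
#' `below24 => below48` holds by construction.
#'
#' @param clicks data.frame with `begin_s`, `end_s`
#' @param spec a [spectrogram()] of the recording the clicks live in
#' @param noise_margin_db detectability margin in dB
#' @param low_edge_hz lower band edge (5 kHz)
#' @return `clicks` with logical columns `below24`, `below48`, `above48`
#'   replaced by the measured judgements
#' @export
census_clicks <- function(clicks, spec, noise_margin_db = 6, low_edge_hz = 5000,
                          min_run_bins = 5) {
  n <- nrow(clicks)
  b24 <- logical(n); b48 <- logical(n)
  for (i in seq_len(n)) {
    b24[i] <- band_occurrence(spec, clicks$begin_s[i], clicks$end_s[i],
                              c(low_edge_hz, 24000), noise_margin_db,
                              min_run_bins = min_run_bins)
    b48[i] <- if (b24[i]) TRUE else
      band_occurrence(spec, clicks$begin_s[i], clicks$end_s[i],
                      c(low_edge_hz, 48000), noise_margin_db,
                      min_run_bins = min_run_bins)
  }
  out <- clicks
  out$below24 <- b24
  out$below48 <- b48
  out$above48 <- TRUE
  out
}

#' Keep only echolocation-regime clicks
#'
#' Removes clicks whose nearest-neighbour inter-click interval (onset to
#' onset) is 10 ms or shorter — the buzz/burst-pulse regime excluded from the
#' echolocation click definition.
#'
#' @param clicks time-sorted data.frame with `begin_s`
#' @param min_ici_s regime boundary (0.01 s)
#' @return the filtered data.frame
#' @export
echolocation_filter <- function(clicks, min_ici_s = 0.01) {
  n <- nrow(clicks)
  if (n <= 1) return(clicks)
  on <- clicks$begin_s
  if (is.unsorted(on)) stop("clicks must be time-sorted")
  gap_prev <- c(Inf, diff(on))
  gap_next <- c(diff(on), Inf)
  keep <- pmin(gap_prev, gap_next) > min_ici_s
  out <- clicks[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tally censused clicks within one sample unit
#'
#' Counts, among clicks falling in the unit, the total and the numbers judged
#' below each threshold under the paired counting rule: a click seen below
#' 24 kHz counts towards both thresholds; one seen only between 24 and
#' 48 kHz counts towards the 48 kHz threshold; one seen only above 48 kHz
#' counts in the total alone.
#'
#' @param sample_unit one row of [segment_samples()]
#' @param clicks censused clicks (with `below24`, `below48` flags)
#' @return data.frame row: `recording_id, index, n_total, n_below24, n_below48`
#' @export
census_sample <- function(sample_unit, clicks) {
  stopifnot(nrow(sample_unit) == 1)
  inside <- clicks$begin_s >= sample_unit$start_s & clicks$begin_s < sample_unit$end_s
  cl <- clicks[inside, , drop = FALSE]
  data.frame(
    recording_id = sample_unit$recording_id,
    index = sample_unit$index,
    n_total = nrow(cl),
    n_below24 = sum(cl$below24),
    n_below48 = sum(cl$below24 | cl$below48),
    stringsAsFactors = FALSE
  )
}

#' Expand census counts into paired proportion records
#'
#' Each sample unit yields two paired rows — frequency thresholds 24 and
#' 48 kHz — with the below-threshold count as numerator and the total click
#' count as denominator. Samples with zero clicks carry no information about
#' the proportion and are excluded (with a message).
#'
#' @param counts data.frame of [census_sample()] rows; may carry
#'   `environment` / `group_id` columns which are passed through
#' @return data.frame with columns `sample_id, recording_id, freq, numerator,
#'   denominator` (+ passthrough columns), `freq` a factor with levels
#'   `"24", "48"`
#' @export
census_to_proportions <- function(counts) {
  if (any(counts$n_total == 0)) {
    message("excluding ", sum(counts$n_total == 0),
            " sample(s) with zero clicks")
    counts <- counts[counts$n_total > 0, , drop = FALSE]
  }
  if (nrow(counts) == 0) {
    return(data.frame(sample_id = character(0), recording_id = character(0),
                      freq = factor(character(0), levels = c("24", "48")),
                      numerator = integer(0), denominator = integer(0)))
  }
  long <- function(freq, num) {
    out <- data.frame(
      sample_id = paste0(counts$recording_id, "#", counts$index),
      recording_id = counts$recording_id,
      freq = factor(freq, levels = c("24", "48")),
      numerator = num,
      denominator = counts$n_total,
      stringsAsFactors = FALSE
    )
    for (extra in intersect(c("environment", "group_id"), names(counts)))
      out[[extra]] <- counts[[extra]]
    out
  }
  rbind(long("24", counts$n_below24), long("48", counts$n_below48))
}
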