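# Audio and annotation I/O: WAV files, Raven-style selection tables, and
# fractionation of recordings into 1-min sample units.

#' Construct a recording object
#'
#' A recording is a mono waveform in \[-1, 1\] with its sampling rate and the
#' identifiers the mixed models group by: recording, group (the dolphin group
#' a recording sampled) and environment (lagoon system or open waters).
#'
#' @param samples numeric vector of amplitudes in \[-1, 1\]
#' @param rate_hz sampling rate in Hz
#' @param recording_id identifier, coerced to character
#' @param environment `"lagoon"` or `"open"`
#' @param group_id identifier of the sampled group
#' @return an object of class `"pam_recording"`
#' @export
recording <- function(samples, rate_hz, recording_id = "rec1",
                      environment = c("lagoon", "open"), group_id = "grp1") {
  environment <- match.arg(environment)
  stopifnot(is.numeric(samples), length(samples) > 0, rate_hz > 0)
  structure(
    list(samples = as.numeric(samples), rate_hz = as.numeric(rate_hz),
         recording_id = as.character(recording_id), environment = environment,
         group_id = as.character(group_id)),
    class = "pam_recording"
  )
}

#' @export
print.pam_recording <- function(x, ...) {
  cat(sprintf("<pam_recording %s> %.3f s @ %g Hz, env=%s, group=%s\n",
              x$recording_id, length(x$samples) / x$rate_hz, x$rate_hz,
              x$environment, x$group_id))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec a `pam_recording`
#' @return seconds
#' @export
rec_duration <- function(rec) length(rec$samples) / rec$rate_hz

#' Write a mono WAV file
#'
#' Supports IEEE float (32-bit) and PCM 16/24-bit encodings. Samples are
#' clipped to \[-1, 1\] for PCM.
#'
#' @param rec a `pam_recording` or numeric vector
#' @param path output file path
#' @param rate_hz sampling rate, required when `rec` is a bare vector
#' @param encoding `"float32"`, `"pcm24"` or `"pcm16"`
#' @return `path`, invisibly
#' @export
write_wav <- function(rec, path, rate_hz = NULL,
                      encoding = c("float32", "pcm24", "pcm16")) {
  encoding <- match.arg(encoding)
  if (inherits(rec, "pam_recording")) {
    x <- rec$samples
    rate_hz <- rec$rate_hz
  } else {
    x <- as.numeric(rec)
    if (is.null(rate_hz)) stop("rate_hz is required when writing a bare vector")
  }
  n <- length(x)
  bits <- switch(encoding, float32 = 32L, pcm24 = 24L, pcm16 = 16L)
  fmt <- if (encoding == "float32") 3L else 1L
  bytes_per_sample <- bits %/% 8L
  data_size <- n * bytes_per_sample
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")              # mono
  writeBin(as.integer(rate_hz), con, size = 4, endian = "little")
  writeBin(as.integer(rate_hz * bytes_per_sample), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per_sample), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (encoding == "float32") {
    writeBin(x, con, size = 4, endian = "little")
  } else if (encoding == "pcm16") {
    v <- as.integer(round(pmax(pmin(x, 1), -1) * 32767))
    writeBin(v, con, size = 2, endian = "little")
  } else { # pcm24: little-endian 3-byte two's complement, packed by hand
    v <- round(pmax(pmin(x, 1), -1) * 8388607)
    v[v < 0] <- v[v < 0] + 16777216
    b <- rbind(v %% 256, (v %/% 256) %% 256, v %/% 65536)
    writeBin(as.raw(b), con)
  }
  invisible(path)
}

#' Read a mono WAV file
#'
#' Parses the RIFF container directly; PCM 16/24/32-bit and IEEE float 32/64
#' encodings are supported. Multi-channel files are reduced to channel 1 with
#' a warning (hydrophone audio is mono).
#'
#' @param path WAV file path
#' @param recording_id,environment,group_id metadata attached to the result
#' @return a [recording()]
#' @export
read_wav <- function(path, recording_id = basename(path),
                     environment = "lagoon", group_id = "grp1") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) < 44) stop("not a WAV file (too short): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  read_tag <- function() {
    b <- readBin(con, raw(), n = 4)
    if (length(b) < 4 || any(b == as.raw(0))) return(NA_character_)
    rawToChar(b)
  }
  if (!identical(read_tag(), "RIFF")) stop("not a RIFF/WAV file: ", path)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (!identical(read_tag(), "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- read_tag()
    if (is.na(id)) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt_raw <- readBin(con, raw(), n = size)
      u16 <- function(i) sum(as.integer(fmt_raw[i:(i + 1)]) * c(1, 256))
      u32 <- function(i) sum(as.integer(fmt_raw[i:(i + 3)]) * c(1, 256, 65536, 16777216))
      fmt <- list(audio_format = u16(1), channels = u16(3),
                  rate = u32(5), bits = u16(15))
    } else if (id == "data") {
      data_raw <- readBin(con, raw(), n = size)
    } else {
      invisible(readBin(con, raw(), n = size + size %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop("no fmt chunk in ", path)
  if (is.null(data_raw) || length(data_raw) == 0) stop("no audio data in ", path)
  x <- decode_wav_samples(data_raw, fmt$audio_format, fmt$bits)
  if (fmt$channels > 1) {
    warning("multi-channel WAV; using channel 1 of ", fmt$channels)
    x <- x[seq(1, length(x), by = fmt$channels)]
  }
  recording(x, fmt$rate, recording_id = recording_id,
            environment = environment, group_id = group_id)
}

decode_wav_samples <- function(raw_data, audio_format, bits) {
  if (audio_format == 3) { # IEEE float
    if (!bits %in% c(32, 64))
      stop("unsupported float WAV bit depth: ", bits)
    readBin(raw_data, numeric(), n = length(raw_data) %/% (bits %/% 8),
            size = bits %/% 8, endian = "little")
  } else if (audio_format == 1) { # integer PCM
    if (bits == 16) {
      readBin(raw_data, integer(), n = length(raw_data) %/% 2, size = 2,
              signed = TRUE, endian = "little") / 32768
    } else if (bits == 24) {
      m <- matrix(as.integer(raw_data), nrow = 3)
      v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
      v[v >= 8388608] <- v[v >= 8388608] - 16777216
      v / 8388608
    } else if (bits == 32) {
      readBin(raw_data, integer(), n = length(raw_data) %/% 4, size = 4,
              endian = "little") / 2147483648
    } else {
      stop("unsupported PCM WAV bit depth: ", bits)
    }
  } else {
    stop("unsupported WAV encoding (audio format tag ", audio_format, ")")
  }
}

#' Fractionate a recording into 1-min sample units
#'
#' Sample units tile the recording without overlap: `floor(T/60)` full 60-s
#' units plus one trailing remainder unit when the duration is not a multiple
#' of 60 s (sub-minute remainders are kept as analysis samples). Intervals
#' are half-open `[start_s, end_s)`.
#'
#' @param rec a `pam_recording`
#' @param unit_s unit length in seconds (60 by default)
#' @return data.frame with columns `recording_id, index, start_s, end_s, duration_s`
#' @export
segment_samples <- function(rec, unit_s = 60) {
  stopifnot(inherits(rec, "pam_recording"), unit_s > 0)
  n <- length(rec$samples)
  unit_n <- round(unit_s * rec$rate_hz)
  starts <- seq(0L, n - 1L, by = unit_n)
  ends <- pmin(starts + unit_n, n)
  data.frame(
    recording_id = rec$recording_id,
    index = seq_along(starts),
    start_s = starts / rec$rate_hz,
    end_s = ends / rec$rate_hz,
    duration_s = (ends - starts) / rec$rate_hz,
    stringsAsFactors = FALSE
  )
}

#' Write a Raven-style selection table
#'
#' Tab-separated with the Raven column dialect (`Selection`, `Begin Time (s)`,
#' `End Time (s)`, `Low Freq (Hz)`, `High Freq (Hz)`) plus any extra columns
#' present (e.g. the `below24` / `below48` ground-truth band flags).
#'
#' @param selections data.frame with at least `begin_s` and `end_s`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_selection_table <- function(selections, path) {
  stopifnot(all(c("begin_s", "end_s") %in% names(selections)))
  n <- nrow(selections)
  out <- data.frame(
    Selection = seq_len(n),
    `Begin Time (s)` = selections$begin_s,
    `End Time (s)` = selections$end_s,
    `Low Freq (Hz)` = if ("low_hz" %in% names(selections)) selections$low_hz else rep(0, n),
    `High Freq (Hz)` = if ("high_hz" %in% names(selections)) selections$high_hz else rep(96000, n),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  for (extra in setdiff(names(selections), c("begin_s", "end_s", "low_hz", "high_hz")))
    out[[extra]] <- selections[[extra]]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a Raven-style selection table
#'
#' @param path tab-separated selection table with columns `Begin Time (s)` and
#'   `End Time (s)` (Raven dialect). Additional columns are carried through
#'   (logical-looking columns such as band flags are preserved).
#' @return data.frame with columns `begin_s`, `end_s` and any extras,
#'   time-sorted. Rows with `end_s <= begin_s` or negative times are an error;
#'   unordered input is sorted with a warning; a header-only file yields an
#'   empty data.frame.
#' @export
read_selection_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("Begin Time (s)", "End Time (s)")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0)
    stop("selection table is missing required column(s): ",
         paste(missing, collapse = ", "))
  out <- data.frame(begin_s = as.numeric(tab[["Begin Time (s)"]]),
                    end_s = as.numeric(tab[["End Time (s)"]]),
                    stringsAsFactors = FALSE)
  renames <- c("Low Freq (Hz)" = "low_hz", "High Freq (Hz)" = "high_hz")
  for (extra in setdiff(names(tab), c("Selection", required))) {
    nm <- if (extra %in% names(renames)) renames[[extra]] else extra
    out[[nm]] <- tab[[extra]]
  }
  if (nrow(out) == 0) return(out)
  if (any(out$end_s <= out$begin_s))
    stop("selection table has row(s) with End Time <= Begin Time")
  if (any(out$begin_s < 0)) stop("selection table has negative times")
  if (is.unsorted(out$begin_s)) {
    warning("selection table rows were not time-sorted; sorting")
    out <- out[order(out$begin_s), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}
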