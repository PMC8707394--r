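# Bridge to Audacity: multi-channel IEEE-float WAV export of the feature
# series, and the tab-separated label-track dialect Audacity exports.
#
# The WAV writer/reader is self-contained base R binary I/O: RIFF container,
# an 18-byte WAVE_FORMAT_IEEE_FLOAT fmt chunk, a fact chunk and interleaved
# 32-bit little-endian floats. One 7-channel file at a nominal 1 Hz sample
# rate imports as seven parallel tracks in a single drag-and-drop.

#' Write a feature series as a multi-channel float WAV
#'
#' Channels are written in canonical order at a 1 Hz header sample rate, as
#' 32-bit IEEE floats, values verbatim (already in \[-1, 1\]). Missing frames
#' are written as 0.0 so tracks stay visually continuous; the missing-mask and
#' the absolute start time go to a JSON sidecar (`<path>.json`) together with
#' subject and channel metadata.
#'
#' @param features a non-empty [feature_series()].
#' @param path output `.wav` path.
#' @param subject_id subject tag stored in the sidecar.
#' @param extra named list merged into the sidecar (e.g. threshold config).
#' @return `path`, invisibly.
#' @export
write_feature_wav <- function(features, path, subject_id = "unknown",
                              extra = list()) {
  stopifnot(inherits(features, "feature_series"))
  n <- nrow(features$channels)
  if (n == 0L) stop("refusing to write an empty feature series", call. = FALSE)
  ch <- features$channels
  ch[is.na(ch)] <- 0
  write_float_wav(t(ch), sample_rate = features$rate, path = path)

  sidecar <- c(list(
    start_time = format(features$start_time, "%Y-%m-%dT%H:%M:%S", usetz = FALSE),
    tz = format(features$start_time, "%Z"),
    subject_id = subject_id,
    sample_rate = features$rate,
    channel_names = colnames(features$channels),
    n_frames = n,
    missing = which(features$missing)
  ), extra)
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(wav_path) paste0(wav_path, ".json")

#' Read a feature WAV back (with its sidecar)
#'
#' @param path `.wav` path written by [write_feature_wav()].
#' @param tz time zone for the sidecar start time.
#' @return A [feature_series()]; frames listed in the sidecar missing-mask are
#'   restored to `NA`.
#' @export
read_feature_wav <- function(path, tz = "UTC") {
  w <- read_float_wav(path)
  sc_path <- sidecar_path(path)
  if (!file.exists(sc_path)) stop(sprintf("sidecar not found: %s", sc_path), call. = FALSE)
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  ch <- t(w$samples)
  miss <- rep(FALSE, nrow(ch))
  if (length(sc$missing)) miss[as.integer(sc$missing)] <- TRUE
  ch[miss, ] <- NA_real_
  feature_series(parse_iso_time(sc$start_time, tz), ch, miss)
}

# ---- low-level RIFF/WAVE float32 I/O ----

write_float_wav <- function(samples_by_channel, sample_rate, path) {
  nch <- nrow(samples_by_channel)
  n <- ncol(samples_by_channel)
  block_align <- nch * 4L
  data_bytes <- n * block_align
  con <- file(path, "wb")
  on.exit(close(con))
  wr_u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wr_u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  writeChar("RIFF", con, eos = NULL)
  wr_u32(4L + (8L + 18L) + (8L + 4L) + (8L + data_bytes))
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  wr_u32(18L)
  wr_u16(3L)                       # WAVE_FORMAT_IEEE_FLOAT
  wr_u16(nch)
  wr_u32(as.integer(sample_rate))
  wr_u32(as.integer(sample_rate) * block_align)  # byte rate
  wr_u16(block_align)
  wr_u16(32L)                      # bits per sample
  wr_u16(0L)                       # cbSize
  writeChar("fact", con, eos = NULL)
  wr_u32(4L)
  wr_u32(n)
  writeChar("data", con, eos = NULL)
  wr_u32(data_bytes)
  writeBin(as.numeric(samples_by_channel), con, size = 4, endian = "little")
  invisible(path)
}

read_float_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd_u32 <- function() readBin(con, "integer", size = 4, endian = "little")
  rd_u16 <- function() readBin(con, "integer", size = 2, signed = FALSE, endian = "little")
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file", call. = FALSE)
  rd_u32()
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file", call. = FALSE)
  fmt <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- rd_u32()
    if (id == "fmt ") {
      fmt <- list(code = rd_u16(), nch = rd_u16(), rate = rd_u32())
      rd_u32(); rd_u16()
      fmt$bits <- rd_u16()
      if (size > 16L) readBin(con, "raw", size - 16L)
    } else if (id == "data") {
      if (is.null(fmt)) stop("malformed WAV: data before fmt", call. = FALSE)
      if (fmt$code != 3L || fmt$bits != 32L) {
        stop("expected 32-bit IEEE float WAV", call. = FALSE)
      }
      vals <- readBin(con, "numeric", n = size / 4L, size = 4, endian = "little")
      samples <- matrix(vals, nrow = fmt$nch)
      if (size %% 2L == 1L) readBin(con, "raw", 1L)
    } else {
      readBin(con, "raw", size + size %% 2L)
    }
    if (!is.null(fmt) && !is.null(samples)) break
  }
  if (is.null(samples)) stop("no data chunk found", call. = FALSE)
  list(sample_rate = fmt$rate, samples = samples)
}

# ---- Audacity label tracks ----

#' Audacity label track
#'
#' An ordered list of labelled regions, offsets in seconds relative to the
#' start of the recording the labels annotate. Entries are kept sorted by
#' start.
#'
#' @param entries data frame with columns `start_s`, `end_s`, `text`.
#' @return An object of class `label_track` (a data frame).
#' @export
label_track <- function(entries) {
  stopifnot(is.data.frame(entries))
  need <- c("start_s", "end_s", "text")
  if (!all(need %in% names(entries))) {
    stop("entries must have columns start_s, end_s, text", call. = FALSE)
  }
  if (any(entries$start_s < 0)) stop("label start must be >= 0", call. = FALSE)
  if (any(entries$end_s < entries$start_s)) {
    stop("label end must be >= start", call. = FALSE)
  }
  entries <- entries[order(entries$start_s, entries$end_s), , drop = FALSE]
  rownames(entries) <- NULL
  entries$text <- as.character(entries$text)
  class(entries) <- c("label_track", "data.frame")
  entries
}

#' Read an Audacity label file
#'
#' One region per line, tab-separated `start<TAB>end<TAB>text`, decimal
#' seconds. Lines are sorted by start on read; Audacity's optional spectral
#' selection lines (starting with `\`) are ignored.
#'
#' @param path label text file.
#' @return A [label_track()].
#' @export
read_label_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "\\")]
  if (!length(lines)) {
    return(label_track(data.frame(start_s = numeric(0), end_s = numeric(0),
                                  text = character(0))))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  parsed <- lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (length(p) < 2L) stop(sprintf("line %d: expected start<TAB>end[<TAB>text]", i),
                             call. = FALSE)
    s <- suppressWarnings(as.numeric(p[1])); e <- suppressWarnings(as.numeric(p[2]))
    if (is.na(s) || is.na(e)) stop(sprintf("line %d: non-numeric label bounds", i),
                                   call. = FALSE)
    if (e < s) stop(sprintf("line %d: end before start", i), call. = FALSE)
    data.frame(start_s = s, end_s = e,
               text = if (length(p) >= 3L) p[3] else "", stringsAsFactors = FALSE)
  })
  label_track(do.call(rbind, parsed))
}

#' Write an Audacity label file
#'
#' Emits the dialect Audacity itself exports: tab-separated fields with
#' 6-decimal seconds, so `read_label_file(write_label_file(x))` is the
#' identity and a second write is byte-identical.
#'
#' @param track a [label_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label_file <- function(track, path) {
  stopifnot(inherits(track, "label_track"))
  lines <- sprintf("%.6f\t%.6f\t%s", track$start_s, track$end_s, track$text)
  writeLines(lines, path)
  invisible(path)
}

#' Convert label regions to absolute in-bed events
#'
#' Each region becomes an event anchored at the recording start time (from
#' the WAV sidecar): `to_bed = start + start_s`, `out_of_bed = start + end_s`.
#' Nights are assigned by the noon rule. Zero-duration and >= 24 h regions
#' are rejected as implausible in-bed periods.
#'
#' @param track a [label_track()].
#' @param recording_start `POSIXct` start of the annotated recording.
#' @param subject_id subject tag.
#' @param source provenance tag (e.g. `"rater2_round1"`).
#' @return An [inbed_events()] data frame.
#' @export
labels_to_events <- function(track, recording_start, subject_id,
                             source = "rater") {
  stopifnot(inherits(track, "label_track"))
  inbed_events(subject_id,
               to_bed = recording_start + track$start_s,
               out_of_bed = recording_start + track$end_s,
               source = source)
}

#' Convert in-bed events back to a label track
#'
#' Inverse of [labels_to_events()] for a given recording start; events before
#' the recording start are rejected.
#'
#' @param events an [inbed_events()] data frame.
#' @param recording_start `POSIXct` start of the recording.
#' @return A [label_track()].
#' @export
events_to_labels <- function(events, recording_start) {
  start_s <- as.numeric(difftime(events$to_bed, recording_start, units = "secs"))
  end_s <- as.numeric(difftime(events$out_of_bed, recording_start, units = "secs"))
  if (any(start_s < 0)) stop("event precedes recording start", call. = FALSE)
  label_track(data.frame(start_s = start_s, end_s = end_s,
                         text = events$source, stringsAsFactors = FALSE))
}
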