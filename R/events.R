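# In-bed events: (to-bed, out-of-bed) timestamp pairs with provenance.

#' Construct a table of in-bed events
#'
#' An in-bed event is one night's (to-bed, out-of-bed) pair, with subject and
#' source provenance. Durations must be positive and under 24 h. When
#' `night_id` is omitted it is assigned by the noon rule (see [night_of()]).
#'
#' @param subject_id character vector.
#' @param to_bed,out_of_bed `POSIXct` vectors.
#' @param source provenance tag, e.g. `"rater1_round1"`, `"zm"`, `"diary"`.
#' @param night_id `Date` vector, or `NULL` to derive from `to_bed`.
#' @return A data frame of class `inbed_events` with columns `subject_id`,
#'   `night_id`, `to_bed`, `out_of_bed`, `source`.
#' @export
inbed_events <- function(subject_id, to_bed, out_of_bed, source = "unknown",
                         night_id = NULL) {
  n <- length(to_bed)
  if (length(out_of_bed) != n) stop("to_bed and out_of_bed lengths differ", call. = FALSE)
  dur <- as.numeric(difftime(out_of_bed, to_bed, units = "hours"))
  if (any(dur <= 0)) {
    stop(sprintf("event %d has non-positive duration", which(dur <= 0)[1L]), call. = FALSE)
  }
  if (any(dur >= 24)) {
    stop(sprintf("event %d spans >= 24 h; implausible in-bed period", which(dur >= 24)[1L]),
         call. = FALSE)
  }
  if (is.null(night_id)) night_id <- night_of(to_bed)
  df <- data.frame(subject_id = rep_len(as.character(subject_id), n),
                   night_id = as.Date(night_id),
                   to_bed = to_bed, out_of_bed = out_of_bed,
                   source = rep_len(as.character(source), n),
                   stringsAsFactors = FALSE)
  class(df) <- c("inbed_events", "data.frame")
  df
}

#' Assign a night identity by the noon rule
#'
#' An overnight event belongs to the calendar date of its evening: an event
#' starting at or after 12:00 local time keeps its own date; one starting
#' before noon (i.e. after midnight) belongs to the previous date.
#'
#' @param ts `POSIXct` vector (local clock time).
#' @return `Date` vector.
#' @export
night_of <- function(ts) {
  lt <- as.POSIXlt(ts)
  d <- as.Date(format(lt, "%Y-%m-%d"))
  d[lt$hour < 12] <- d[lt$hour < 12] - 1L
  d
}

#' Read/write in-bed events in tidy long form
#'
#' The tidy interchange format has one row per endpoint:
#' `subject,night,source,endpoint,timestamp` with `endpoint` in
#' `{to_bed, out_of_bed}` and ISO-8601 timestamps.
#'
#' @param events an `inbed_events` data frame (or a list of them).
#' @param path file path.
#' @param tz time zone used to render/parse timestamps.
#' @return `write_events_csv()` returns `path` invisibly;
#'   `read_events_csv()` returns a named list of `inbed_events`, one per
#'   source.
#' @export
write_events_csv <- function(events, path, tz = "UTC") {
  if (inherits(events, "inbed_events")) events <- list(events)
  rows <- do.call(rbind, lapply(events, function(e) {
    data.frame(
      subject = rep(e$subject_id, 2L),
      night = rep(as.character(e$night_id), 2L),
      source = rep(e$source, 2L),
      endpoint = rep(c("to_bed", "out_of_bed"), each = nrow(e)),
      timestamp = format(c(e$to_bed, e$out_of_bed), "%Y-%m-%dT%H:%M:%S", tz = tz),
      stringsAsFactors = FALSE
    )
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path, tz = "UTC") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "night", "source", "endpoint", "timestamp")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df$timestamp <- parse_iso_time(df$timestamp, tz)
  out <- lapply(split(df, df$source), function(s) {
    tb <- s[s$endpoint == "to_bed", ]
    ob <- s[s$endpoint == "out_of_bed", ]
    key <- paste(tb$subject, tb$night)
    okey <- paste(ob$subject, ob$night)
    ob <- ob[match(key, okey), ]
    if (anyNA(ob$timestamp)) stop("unpaired endpoints in events CSV", call. = FALSE)
    inbed_events(tb$subject, tb$timestamp, ob$timestamp,
                 source = s$source[1L], night_id = as.Date(tb$night))
  })
  out
}
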