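# Reference in-bed events from EEG epoch records (Zmachine-style, 30-s
# sleep-stage epochs with a sensor-problem code) and from sleep diaries.

ZM_STAGES <- c("WAKE", "LIGHT", "DEEP", "REM", "SENSOR_PROBLEM")
ZM_EPOCH_S <- 30

#' Parse a Zmachine-style epoch CSV into nights
#'
#' Schema: `subject,night,epoch_start,stage`, one row per 30-s epoch,
#' ISO-8601 epoch start times, stages in
#' `WAKE, LIGHT, DEEP, REM, SENSOR_PROBLEM`. Epochs are grouped by
#' (subject, night) and must be contiguous on the 30-s grid; a night that is
#' not contiguous is dropped with a warning and recorded in the
#' `"rejected"` attribute of the result. An unknown stage code is an error.
#'
#' @param path epoch CSV path.
#' @param tz time zone of the epoch timestamps.
#' @return A list of `zm_night` objects (fields `subject_id`, `night_id`,
#'   `epochs`), with attribute `rejected` naming dropped nights.
#' @export
parse_zm_csv <- function(path, tz = "UTC") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "night", "epoch_start", "stage")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df$epoch_start <- parse_iso_time(df$epoch_start, tz)
  as_zm_nights(df)
}

#' Group validated epoch rows into nights
#'
#' @param df data frame with columns `subject`, `night`, `epoch_start`
#'   (`POSIXct`) and `stage`.
#' @return As [parse_zm_csv()].
#' @export
as_zm_nights <- function(df) {
  bad <- setdiff(unique(df$stage), ZM_STAGES)
  if (length(bad)) {
    stop(sprintf("unknown sleep stage code: %s", paste(bad, collapse = ", ")), call. = FALSE)
  }
  pieces <- split(df, paste(df$subject, df$night, sep = "\r"))
  rejected <- character(0)
  nights <- list()
  for (p in pieces) {
    p <- p[order(p$epoch_start), ]
    dt <- diff(as.numeric(p$epoch_start))
    if (length(dt) && any(abs(dt - ZM_EPOCH_S) > 1e-6)) {
      rejected <- c(rejected, sprintf("%s/%s: non-contiguous epochs", p$subject[1], p$night[1]))
      warning(sprintf("dropping night %s/%s: non-contiguous epochs",
                      p$subject[1], p$night[1]), call. = FALSE)
      next
    }
    nights[[length(nights) + 1L]] <- structure(
      list(subject_id = as.character(p$subject[1]),
           night_id = as.Date(p$night[1]),
           epochs = data.frame(start = p$epoch_start, stage = p$stage,
                               stringsAsFactors = FALSE)),
      class = "zm_night")
  }
  ord <- order(vapply(nights, function(n) paste(n$subject_id, n$night_id), ""))
  structure(nights[ord], rejected = rejected)
}

#' @export
print.zm_night <- function(x, ...) {
  cat(sprintf("<zm_night> %s night %s: %d epochs (%d sensor-problem)\n",
              x$subject_id, format(x$night_id), nrow(x$epochs),
              sum(x$epochs$stage == "SENSOR_PROBLEM")))
  invisible(x)
}

#' Derive the in-bed event from one night of EEG epochs
#'
#' The to-bed time is the start of the first non-sensor-problem epoch and the
#' out-of-bed time is the end (start + 30 s) of the last non-sensor-problem
#' epoch, treating each epoch as an interval. A night whose first or last
#' recorded epoch is flagged `SENSOR_PROBLEM` is discarded (the device state
#' at the boundary is unknown), as is a night with no valid epoch at all;
#' sensor problems strictly in the interior leave the endpoints untouched.
#'
#' @param night a `zm_night` from [parse_zm_csv()].
#' @return A list of class `zm_derivation`: `status` (`"ok"` or
#'   `"discarded"`), `reason` (`NA` when ok), and `event` (an
#'   [inbed_events()] row, or `NULL` when discarded).
#' @export
derive_inbed_from_zm <- function(night) {
  stopifnot(inherits(night, "zm_night"))
  ok <- night$epochs$stage != "SENSOR_PROBLEM"
  n <- nrow(night$epochs)
  discard <- function(reason) {
    structure(list(status = "discarded", reason = reason, event = NULL,
                   subject_id = night$subject_id, night_id = night$night_id),
              class = "zm_derivation")
  }
  if (!any(ok)) return(discard("all epochs are sensor problems"))
  if (!ok[1L]) return(discard("recording begins with a sensor problem"))
  if (!ok[n]) return(discard("recording ends with a sensor problem"))
  first <- which(ok)[1L]
  last <- which(ok)[sum(ok)]
  ev <- inbed_events(night$subject_id,
                     to_bed = night$epochs$start[first],
                     out_of_bed = night$epochs$start[last] + ZM_EPOCH_S,
                     source = "zm", night_id = night$night_id)
  structure(list(status = "ok", reason = NA_character_, event = ev,
                 subject_id = night$subject_id, night_id = night$night_id),
            class = "zm_derivation")
}

#' @export
print.zm_derivation <- function(x, ...) {
  if (x$status == "ok") {
    cat(sprintf("<zm_derivation> %s night %s: %s -> %s\n", x$subject_id,
                format(x$night_id), format(x$event$to_bed, "%H:%M:%S"),
                format(x$event$out_of_bed, "%H:%M:%S")))
  } else {
    cat(sprintf("<zm_derivation> %s night %s: DISCARDED (%s)\n",
                x$subject_id, format(x$night_id), x$reason))
  }
  invisible(x)
}

#' Derive in-bed events for a batch of EEG nights
#'
#' @param nights list of `zm_night` objects.
#' @return An [inbed_events()] data frame of the kept nights, with attribute
#'   `discarded`: a data frame of (subject, night, reason) for dropped
#'   nights.
#' @export
zm_events <- function(nights) {
  ders <- lapply(nights, derive_inbed_from_zm)
  kept <- Filter(function(d) d$status == "ok", ders)
  drop <- Filter(function(d) d$status != "ok", ders)
  ev <- if (length(kept)) {
    do.call(rbind, lapply(kept, function(d) d$event))
  } else {
    inbed_events(character(0), as.POSIXct(character(0)), as.POSIXct(character(0)))[0, ]
  }
  class(ev) <- c("inbed_events", "data.frame")
  attr(ev, "discarded") <- data.frame(
    subject = vapply(drop, function(d) d$subject_id, ""),
    night = vapply(drop, function(d) format(d$night_id), ""),
    reason = vapply(drop, function(d) d$reason, ""),
    stringsAsFactors = FALSE)
  ev
}

#' Parse a sleep-diary CSV
#'
#' Schema: `subject,date,to_bed,out_of_bed`, with `date` the evening
#' (night) date and clock times `HH:MM`. A to-bed clock before noon is taken
#' to fall on the morning after `date`; an out-of-bed clock at or before the
#' to-bed time rolls over to the next day. Rows with a missing endpoint are
#' flagged incomplete, excluded from the result and returned in the
#' `"incomplete"` attribute.
#'
#' @param path diary CSV path.
#' @param tz time zone of the reported clock times.
#' @return An [inbed_events()] data frame with source `"diary"`.
#' @export
parse_diary <- function(path, tz = "UTC") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("subject", "date", "to_bed", "out_of_bed")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  incomplete <- !nzchar(trimws(df$to_bed)) | !nzchar(trimws(df$out_of_bed)) |
    is.na(df$to_bed) | is.na(df$out_of_bed)
  if (any(incomplete)) {
    warning(sprintf("%d incomplete diary entr%s excluded",
                    sum(incomplete), ifelse(sum(incomplete) == 1, "y", "ies")),
            call. = FALSE)
  }
  keep <- df[!incomplete, , drop = FALSE]
  tb_min <- parse_clock(keep$to_bed, "to_bed")
  ob_min <- parse_clock(keep$out_of_bed, "out_of_bed")
  night <- as.Date(keep$date)
  if (anyNA(night)) stop("unparsable diary date", call. = FALSE)
  base <- as.POSIXct(paste(night, "00:00:00"), tz = tz)
  to_bed <- base + ifelse(tb_min >= 720, tb_min, tb_min + 1440) * 60
  out_of_bed <- as.POSIXct(format(to_bed, "%Y-%m-%d"), tz = tz) + ob_min * 60
  roll <- out_of_bed <= to_bed
  out_of_bed[roll] <- out_of_bed[roll] + 86400
  ev <- inbed_events(keep$subject, to_bed, out_of_bed, source = "diary",
                     night_id = night)
  attr(ev, "incomplete") <- df[incomplete, , drop = FALSE]
  ev
}

# "HH:MM" (or "HH:MM:SS") -> minutes past midnight
parse_clock <- function(x, what) {
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})(?::([0-9]{2}))?$", x))
  bad <- vapply(m, length, 0L) == 0L
  if (any(bad)) {
    stop(sprintf("row %d: unparsable %s clock time '%s'",
                 which(bad)[1L], what, x[which(bad)[1L]]), call. = FALSE)
  }
  hh <- as.numeric(vapply(m, `[`, "", 2L))
  mm <- as.numeric(vapply(m, `[`, "", 3L))
  ss <- vapply(m, `[`, "", 4L)
  ss <- ifelse(nzchar(ss), as.numeric(ss), 0)
  if (any(hh > 23 | mm > 59)) {
    bad <- which(hh > 23 | mm > 59)[1L]
    stop(sprintf("row %d: %s clock time out of range '%s'", bad, what, x[bad]), call. = FALSE)
  }
  hh * 60 + mm + ss / 60
}
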