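# Tri-axial accelerometer recordings: container, CSV reader, resampler.

#' Tri-axial accelerometer recording
#'
#' Container for a timestamped tri-axial acceleration stream from one body
#' site. The x axis is the longitudinal axis of the body segment (positive
#' toward the head when upright); units are g. Sample times are stored as
#' numeric second offsets from `start_time`, so non-uniform streams (as read
#' from CSV) and uniform streams (after [resample_recording()]) share one
#' representation.
#'
#' @param site `"hip"` or `"thigh"`.
#' @param start_time `POSIXct` timestamp of the first sample.
#' @param xyz numeric matrix with columns `ax`, `ay`, `az` in g.
#' @param sample_rate sampling frequency in Hz (`NA` if non-uniform).
#' @param time numeric second offsets of each sample from `start_time`;
#'   defaults to a uniform grid at `sample_rate`.
#' @param gaps data frame with columns `start`, `end` (second offsets) marking
#'   stretches where the inter-sample interval exceeded twice the nominal
#'   period.
#' @param clip if `TRUE`, components beyond the +/- 8 g sensor range are
#'   clamped (with a warning); if `FALSE` they are an error.
#'
#' @return An object of class `accel_recording`.
#' @export
accel_recording <- function(site, start_time, xyz, sample_rate = NA_real_,
                            time = NULL, gaps = NULL, clip = TRUE) {
  site <- match.arg(site, c("hip", "thigh"))
  if (!inherits(start_time, "POSIXct") || length(start_time) != 1L) {
    stop("`start_time` must be a single POSIXct timestamp", call. = FALSE)
  }
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) stop("`xyz` must have three columns (ax, ay, az)", call. = FALSE)
  colnames(xyz) <- c("ax", "ay", "az")
  storage.mode(xyz) <- "double"
  if (anyNA(xyz) || any(!is.finite(xyz))) {
    stop("acceleration samples must all be finite", call. = FALSE)
  }
  xyz <- clip_to_range(xyz, clip)
  if (is.null(time)) {
    if (!is.finite(sample_rate) || sample_rate <= 0) {
      stop("`sample_rate` must be > 0 when `time` is not given", call. = FALSE)
    }
    time <- seq(0, by = 1 / sample_rate, length.out = nrow(xyz))
  }
  if (length(time) != nrow(xyz)) stop("`time` length must match rows of `xyz`", call. = FALSE)
  if (is.null(gaps)) gaps <- data.frame(start = numeric(0), end = numeric(0))
  structure(
    list(site = site, start_time = start_time, sample_rate = sample_rate,
         time = as.numeric(time), xyz = xyz, gaps = gaps),
    class = "accel_recording"
  )
}

# +/- 8 g sensor range: clamp (default) or reject
clip_to_range <- function(xyz, clip, range_g = 8) {
  out <- abs(xyz) > range_g
  if (any(out)) {
    if (!clip) stop(sprintf("%d samples exceed the +/-%g g sensor range", sum(out), range_g),
                    call. = FALSE)
    warning(sprintf("clamped %d sample components to +/-%g g", sum(out), range_g),
            call. = FALSE)
    xyz[xyz > range_g] <- range_g
    xyz[xyz < -range_g] <- -range_g
  }
  xyz
}

#' @export
print.accel_recording <- function(x, ...) {
  dur <- if (length(x$time)) x$time[length(x$time)] else 0
  cat(sprintf("<accel_recording> site=%s  n=%d  rate=%s Hz  start=%s  span=%.1f s\n",
              x$site, nrow(x$xyz),
              ifelse(is.na(x$sample_rate), "irregular", format(x$sample_rate)),
              format(x$start_time, "%Y-%m-%d %H:%M:%OS"), dur))
  if (nrow(x$gaps)) cat(sprintf("  %d gap(s) flagged\n", nrow(x$gaps)))
  invisible(x)
}

#' @export
length.accel_recording <- function(x) nrow(x$xyz)

#' Read a tri-axial accelerometer CSV
#'
#' Reads a raw acceleration stream with header `timestamp,ax,ay,az`
#' (ISO-8601 timestamps, components in g). The sample rate is inferred as the
#' reciprocal of the median inter-sample interval unless declared. Intervals
#' longer than twice the nominal period are flagged as gaps and later
#' propagate as missing feature frames.
#'
#' @param path file path.
#' @param site `"hip"` or `"thigh"`.
#' @param sample_rate declared rate in Hz, or `NULL` to infer.
#' @param tz time zone of the timestamps (default `"UTC"`).
#' @param clip clamp values beyond +/- 8 g instead of rejecting.
#' @return An [accel_recording()].
#' @export
read_accel_csv <- function(path, site, sample_rate = NULL, tz = "UTC", clip = TRUE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("timestamp", "ax", "ay", "az")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  if (nrow(df) == 0L) stop("empty recording", call. = FALSE)
  ts <- parse_iso_time(df$timestamp, tz)
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1L]
    stop(sprintf("unparsable timestamp at data line %d: %s", bad, df$timestamp[bad]),
         call. = FALSE)
  }
  off <- as.numeric(ts) - as.numeric(ts[1L])
  if (is.unsorted(off, strictly = TRUE)) {
    bad <- which(diff(off) <= 0)[1L] + 1L
    stop(sprintf("non-monotone timestamps at data line %d", bad), call. = FALSE)
  }
  if (is.null(sample_rate)) {
    sample_rate <- if (nrow(df) > 1L) 1 / stats::median(diff(off)) else NA_real_
  }
  gaps <- data.frame(start = numeric(0), end = numeric(0))
  if (nrow(df) > 1L && is.finite(sample_rate)) {
    dt <- diff(off)
    big <- which(dt > 2 / sample_rate)
    gaps <- data.frame(start = off[big], end = off[big + 1L])
  }
  accel_recording(site = site, start_time = ts[1L],
                  xyz = cbind(ax = df$ax, ay = df$ay, az = df$az),
                  sample_rate = sample_rate, time = off, gaps = gaps, clip = clip)
}

parse_iso_time <- function(x, tz) {
  ts <- as.POSIXct(x, tz = tz, format = "%Y-%m-%dT%H:%M:%OS")
  alt <- is.na(ts)
  if (any(alt)) ts[alt] <- as.POSIXct(x[alt], tz = tz, format = "%Y-%m-%d %H:%M:%OS")
  ts
}

#' Resample a recording onto a uniform grid
#'
#' Linear interpolation onto a uniform grid at `target_hz`, starting at the
#' recording's `start_time`. Used to reconcile the native device rate with the
#' 30 Hz grid the windowed feature pipeline assumes (60 samples per 2-s
#' window). Gap annotations are preserved.
#'
#' @param rec an [accel_recording()].
#' @param target_hz target rate in Hz (default 30).
#' @return A uniform [accel_recording()] at `target_hz`.
#' @export
resample_recording <- function(rec, target_hz = 30) {
  stopifnot(inherits(rec, "accel_recording"))
  if (!is.finite(target_hz) || target_hz <= 0) stop("`target_hz` must be > 0", call. = FALSE)
  if (nrow(rec$xyz) == 0L) stop("cannot resample an empty recording", call. = FALSE)
  span <- rec$time[length(rec$time)]
  n_out <- floor(span * target_hz + 1e-9) + 1L
  grid <- seq(0, by = 1 / target_hz, length.out = n_out)
  xyz <- vapply(1:3, function(j) {
    stats::approx(rec$time, rec$xyz[, j], xout = grid, rule = 2)$y
  }, numeric(n_out))
  colnames(xyz) <- c("ax", "ay", "az")
  accel_recording(site = rec$site, start_time = rec$start_time, xyz = xyz,
                  sample_rate = target_hz, time = grid, gaps = rec$gaps)
}

# interpolate a recording at absolute POSIXct times (used to align two sites)
interp_at <- function(rec, times_abs) {
  off <- as.numeric(times_abs) - as.numeric(rec$start_time)
  xyz <- vapply(1:3, function(j) {
    stats::approx(rec$time, rec$xyz[, j], xout = off, rule = 2)$y
  }, numeric(length(off)))
  colnames(xyz) <- c("ax", "ay", "az")
  xyz
}

#' Write a recording as CSV
#'
#' Inverse of [read_accel_csv()]; emits `timestamp,ax,ay,az` with ISO-8601
#' timestamps at millisecond precision.
#'
#' @param rec an [accel_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_accel_csv <- function(rec, path) {
  stopifnot(inherits(rec, "accel_recording"))
  ts <- rec$start_time + rec$time
  # %OS truncates fractional seconds; nudge by half the printed resolution
  df <- data.frame(timestamp = format(ts + 5e-4, "%Y-%m-%dT%H:%M:%OS3"),
                   ax = rec$xyz[, 1], ay = rec$xyz[, 2], az = rec$xyz[, 3])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
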