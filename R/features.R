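# The seven visual signal features at 1-s resolution:
# Lying, Activity, Time, Thigh-SDacc, Thigh-Inclination, Hip-SDacc,
# Hip-Inclination, each encoded into [-1, 1] for display as audio tracks.

FEATURE_CHANNELS <- c("Lying", "Activity", "Time",
                      "Thigh-SDacc", "Thigh-Inclination",
                      "Hip-SDacc", "Hip-Inclination")

#' Feature series container
#'
#' Seven encoded signal channels at 1 Hz. Every value lies in \[-1, 1\];
#' frames that cannot be computed (recording gaps, undefined inclination) are
#' `NA` here and are written as 0 with a sidecar missing-mask on WAV export.
#'
#' @param start_time `POSIXct` time of the first frame (the center of the
#'   first 2-s window).
#' @param channels numeric matrix, one column per channel in canonical order.
#' @param missing logical vector marking frames with no valid value.
#' @return An object of class `feature_series`.
#' @export
feature_series <- function(start_time, channels, missing = NULL) {
  channels <- as.matrix(channels)
  if (ncol(channels) != 7L) stop("`channels` must have seven columns", call. = FALSE)
  colnames(channels) <- FEATURE_CHANNELS
  if (is.null(missing)) missing <- rowSums(is.na(channels)) > 0
  if (nrow(channels) && any(!missing)) {
    rng <- range(channels[!missing, ], na.rm = TRUE)
    if (rng[1] < -1 - 1e-12 || rng[2] > 1 + 1e-12) {
      stop("encoded channel values must lie in [-1, 1]", call. = FALSE)
    }
  }
  structure(list(start_time = start_time, rate = 1, channels = channels,
                 missing = as.logical(missing)),
            class = "feature_series")
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("<feature_series> %d frames @ 1 Hz from %s (%d missing)\n",
              nrow(x$channels), format(x$start_time, "%Y-%m-%d %H:%M:%S"),
              sum(x$missing)))
  invisible(x)
}

#' @export
length.feature_series <- function(x) nrow(x$channels)

#' Split a uniform recording into overlapping analysis windows
#'
#' Windows are 2 s long (60 samples at 30 Hz) with 50% overlap (hop 30
#' samples), giving one feature frame per second. A trailing partial window
#' is dropped; fewer samples than one window yields an empty list.
#'
#' @param rec a uniform [accel_recording()] (nominally 30 Hz).
#' @return List of 60 x 3 matrices, each with a `center_time` attribute.
#' @export
frame_windows <- function(rec) {
  stopifnot(inherits(rec, "accel_recording"))
  rate <- rec$sample_rate
  if (!is.finite(rate)) stop("recording must be uniform (resample first)", call. = FALSE)
  w <- as.integer(round(2 * rate)); h <- as.integer(round(rate))
  n <- nrow(rec$xyz)
  k <- n_frames(n, w, h)
  lapply(seq_len(k), function(i) {
    idx <- ((i - 1L) * h + 1L):((i - 1L) * h + w)
    win <- rec$xyz[idx, , drop = FALSE]
    attr(win, "center_time") <- rec$start_time + ((i - 1L) * h + w / 2) / rate
    win
  })
}

n_frames <- function(n, w = 60L, h = 30L) {
  if (n < w) 0L else as.integer((n - w) %/% h) + 1L
}

#' Inclination angle of a window
#'
#' Angle in degrees between the device's longitudinal (x) axis and the mean
#' acceleration vector over the window: `acos(mean_x / ||mean||)`. Under
#' quasi-static conditions the mean acceleration is gravity, so this is the
#' segment's tilt from upright: 0 aligned, 90 horizontal, 180 inverted.
#'
#' @param window numeric matrix of samples (columns ax, ay, az).
#' @return Degrees in \[0, 180\], or `NA` if the mean vector has zero
#'   magnitude (undefined inclination, propagated as a missing frame).
#' @export
inclination_deg <- function(window) {
  m <- colMeans(window)
  nrm <- sqrt(sum(m^2))
  if (nrm == 0) return(NA_real_)
  acos(max(-1, min(1, m[1] / nrm))) * 180 / pi
}

#' Standard deviation of the longitudinal acceleration
#'
#' Population SD (divide by n) of the x-axis samples in a window; the
#' movement-intensity proxy behind the SDacc channels and the activity
#' classifier.
#'
#' @param window numeric matrix of samples (columns ax, ay, az).
#' @return SD in g.
#' @export
sd_longitudinal <- function(window) {
  x <- window[, 1]
  sqrt(max(0, mean(x^2) - mean(x)^2))
}

#' Classify activity type from thigh inclination and movement
#'
#' Decision rule in the style of the thigh-accelerometer posture classifiers
#' used for free-living actigraphy: an upright thigh means standing, moving or
#' walking (all encoded +1); a tilted, still thigh means sitting (0); a tilted,
#' moving thigh is other activity (-1). Thresholds default to a 45 degree
#' sit boundary and 0.1 g movement boundary and are configurable.
#'
#' @param thigh_incl_deg thigh inclination, degrees.
#' @param thigh_sd_g thigh longitudinal SD, g.
#' @param hip_sd_g hip longitudinal SD, g; reserved for refinements of the
#'   moving/walking split, not used by the default rule.
#' @param theta_sit sit/upright inclination boundary (degrees).
#' @param s_move movement SD boundary (g).
#' @return Integer vector: +1 upright (standing/moving/walking), 0 sitting,
#'   -1 other activity.
#' @export
classify_activity <- function(thigh_incl_deg, thigh_sd_g, hip_sd_g = NULL,
                              theta_sit = 45, s_move = 0.1) {
  ifelse(thigh_incl_deg <= theta_sit, 1L,
         ifelse(thigh_sd_g <= s_move, 0L, -1L))
}

#' Classify lying from hip inclination and concurrent activity
#'
#' A frame is "lying" when the hip inclination strictly exceeds 65 degrees
#' and the thigh is concurrently classified as sitting. Both conditions are
#' needed: a reclined hip with an upright or moving thigh is not lying.
#'
#' @param hip_incl_deg hip inclination, degrees.
#' @param activity activity class from [classify_activity()].
#' @param hip_lying_deg hip inclination threshold (degrees, strict `>`).
#' @return Logical vector.
#' @export
classify_lying <- function(hip_incl_deg, activity, hip_lying_deg = 65) {
  hip_incl_deg > hip_lying_deg & activity == 0L
}

#' Time-of-day channel level
#'
#' The 24-h cycle is split into six left-closed, right-open 4-h bins in local
#' clock time, mapped to six equally spaced levels from -1 (00:00-04:00) to
#' +1 (20:00-24:00).
#'
#' @param timestamp `POSIXct` vector carrying local clock time.
#' @return Levels in \{-1, -0.6, -0.2, 0.2, 0.6, 1\}.
#' @export
time_bin_level <- function(timestamp) {
  lt <- as.POSIXlt(timestamp)
  secs <- lt$hour * 3600 + lt$min * 60 + lt$sec
  bin <- floor(secs / 14400)  # 4-h bins, 0..5
  -1 + 0.4 * bin
}

#' Encode a raw feature value into the [-1, 1] display range
#'
#' Inclination maps as theta/180 into \[0, 1\] (the negative half of the
#' display range is unused: no sign convention distinguishes forward from
#' backward lean). SDacc maps 0 g to -1 ("no movement") and saturates at
#' `sd_max`. Lying is +1/-1; activity class and time level pass through
#' verbatim.
#'
#' @param value raw value(s), valid for the channel kind.
#' @param kind one of `"inclination"`, `"sd"`, `"lying"`, `"activity"`,
#'   `"time"`.
#' @param sd_max saturation point of the SDacc encoding, g.
#' @return Encoded value(s) in \[-1, 1\]; `NA` passes through.
#' @export
encode_feature <- function(value, kind = c("inclination", "sd", "lying",
                                           "activity", "time"),
                           sd_max = 0.5) {
  kind <- match.arg(kind)
  ok <- !is.na(value)
  switch(kind,
    inclination = {
      if (any(ok & (value < 0 | value > 180)))
        stop("inclination must be in [0, 180] degrees", call. = FALSE)
      value / 180
    },
    sd = {
      if (any(ok & value < 0)) stop("SD must be non-negative", call. = FALSE)
      -1 + 2 * pmin(value, sd_max) / sd_max
    },
    lying = ifelse(value, 1, -1),
    activity = {
      if (any(ok & !value %in% c(-1L, 0L, 1L)))
        stop("activity class must be -1, 0 or +1", call. = FALSE)
      as.numeric(value)
    },
    time = {
      lv <- seq(-1, 1, by = 0.4)
      if (any(ok & vapply(value, function(v) min(abs(v - lv)), 0) > 1e-9))
        stop("time level must be one of the six bin levels", call. = FALSE)
      as.numeric(value)
    }
  )
}

#' Build the seven-channel feature series from a hip and a thigh recording
#'
#' Both recordings are resampled to a common 30 Hz grid on their overlapping
#' span and windowed in lockstep (2-s windows, 1-s hop). Per frame, the
#' window-mean inclination and longitudinal SD of each site feed the activity
#' and lying classifiers; all channels are encoded into \[-1, 1\] in canonical
#' order. Frames overlapping a flagged gap at either site, or with undefined
#' inclination, are marked missing.
#'
#' @param hip,thigh [accel_recording()] objects for the two sites.
#' @param target_hz internal analysis rate (default 30, giving the canonical
#'   60-sample window).
#' @param theta_sit,s_move activity-classifier thresholds, see
#'   [classify_activity()].
#' @param hip_lying_deg lying threshold, see [classify_lying()].
#' @param sd_max SDacc encoding saturation, see [encode_feature()].
#' @return A [feature_series()].
#' @export
build_features <- function(hip, thigh, target_hz = 30,
                           theta_sit = 45, s_move = 0.1,
                           hip_lying_deg = 65, sd_max = 0.5) {
  stopifnot(inherits(hip, "accel_recording"), inherits(thigh, "accel_recording"))
  hip_end <- as.numeric(hip$start_time) + hip$time[length(hip$time)]
  thigh_end <- as.numeric(thigh$start_time) + thigh$time[length(thigh$time)]
  t0 <- max(as.numeric(hip$start_time), as.numeric(thigh$start_time))
  t1 <- min(hip_end, thigh_end)
  if (t1 <= t0) stop("recordings do not overlap in time", call. = FALSE)

  start <- hip$start_time + (t0 - as.numeric(hip$start_time))  # POSIXct at t0
  m <- floor((t1 - t0) * target_hz + 1e-9) + 1L
  grid_abs <- start + seq(0, by = 1 / target_hz, length.out = m)
  hx <- interp_at(hip, grid_abs)
  tx <- interp_at(thigh, grid_abs)

  w <- as.integer(round(2 * target_hz)); h <- as.integer(round(target_hz))
  k <- n_frames(m, w, h)
  if (k == 0L) {
    return(feature_series(start, matrix(numeric(0), 0, 7), logical(0)))
  }

  hs <- window_stats(hx, w, h, k)
  ts_ <- window_stats(tx, w, h, k)
  frame_time <- start + seq_len(k)  # window centers, 1-s spacing

  activity <- classify_activity(ts_$incl, ts_$sd, hs$sd, theta_sit, s_move)
  lying <- classify_lying(hs$incl, activity, hip_lying_deg)

  ch <- cbind(
    encode_feature(lying, "lying"),
    encode_feature(activity, "activity"),
    encode_feature(time_bin_level(frame_time), "time"),
    encode_feature(ts_$sd, "sd", sd_max),
    encode_feature(ts_$incl, "inclination"),
    encode_feature(hs$sd, "sd", sd_max),
    encode_feature(hs$incl, "inclination")
  )

  miss <- is.na(hs$incl) | is.na(ts_$incl) |
    frames_in_gaps(k, start, hip) | frames_in_gaps(k, start, thigh)
  ch[miss, ] <- NA_real_
  feature_series(frame_time[1L], ch, miss)
}

# vectorized per-window mean inclination and longitudinal SD via cumulative sums
window_stats <- function(xyz, w, h, k) {
  idx0 <- (seq_len(k) - 1L) * h
  cs <- apply(rbind(0, xyz), 2, cumsum)
  wsum <- cs[idx0 + w + 1L, , drop = FALSE] - cs[idx0 + 1L, , drop = FALSE]
  mu <- wsum / w
  cs2 <- cumsum(c(0, xyz[, 1]^2))
  msq <- (cs2[idx0 + w + 1L] - cs2[idx0 + 1L]) / w
  sdx <- sqrt(pmax(0, msq - mu[, 1]^2))
  nrm <- sqrt(rowSums(mu^2))
  incl <- ifelse(nrm == 0, NA_real_,
                 acos(pmax(-1, pmin(1, mu[, 1] / nrm))) * 180 / pi)
  list(incl = incl, sd = sdx)
}

# frames whose 2-s window overlaps a flagged recording gap
frames_in_gaps <- function(k, start, rec) {
  if (!nrow(rec$gaps)) return(rep(FALSE, k))
  off <- as.numeric(start) - as.numeric(rec$start_time)
  f_start <- (seq_len(k) - 1L) + off   # window start offsets in rec's frame
  f_end <- f_start + 2
  hit <- rep(FALSE, k)
  for (g in seq_len(nrow(rec$gaps))) {
    hit <- hit | (f_start < rec$gaps$end[g] & f_end > rec$gaps$start[g])
  }
  hit
}

#' Propose in-bed label regions from the Lying channel
#'
#' Machine proposal for the manual annotation workflow: sustained runs of
#' Lying = +1 (missing frames are bridged), merged across short interruptions
#' and filtered by a minimum duration, become candidate in-bed regions on the
#' label track. Offsets are seconds relative to the series start, matching the
#' exported WAV timeline.
#'
#' @param features a [feature_series()].
#' @param min_minutes minimum in-bed duration to keep (default 30).
#' @param max_gap_s interruptions up to this length are merged (default 300).
#' @return A [label_track()] of proposed regions labelled `"inbed"`.
#' @export
propose_inbed_labels <- function(features, min_minutes = 30, max_gap_s = 300) {
  stopifnot(inherits(features, "feature_series"))
  lying <- features$channels[, "Lying"]
  lying[is.na(lying)] <- -1
  on <- lying > 0
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (!nrow(runs)) return(label_track(data.frame(start_s = numeric(0),
                                                 end_s = numeric(0),
                                                 text = character(0))))
  merged <- runs[1, , drop = FALSE]
  for (i in seq_len(nrow(runs))[-1]) {
    if (runs$start[i] - merged$end[nrow(merged)] - 1L <= max_gap_s) {
      merged$end[nrow(merged)] <- runs$end[i]
    } else {
      merged <- rbind(merged, runs[i, ])
    }
  }
  keep <- (merged$end - merged$start + 1L) >= min_minutes * 60
  merged <- merged[keep, , drop = FALSE]
  label_track(data.frame(start_s = as.numeric(merged$start - 1L),
                         end_s = as.numeric(merged$end),
                         text = rep("inbed", nrow(merged))))
}
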