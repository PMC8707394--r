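# Seeded simulator: multi-day behavior timelines with known in-bed
# intervals, rendered two-site accelerometry, rater annotations, diary
# entries and EEG epoch records. Every other module is testable against
# these fixtures without any study data.

#' Simulation configuration
#'
#' Defaults emulate a free-living cohort mixing children and adults wearing
#' hip and thigh sensors for a week: subject-level mean bedtimes spread
#' widely across the evening (between-subject SD 90 min around 22:30),
#' night-to-night variation of 30 min, rater annotation error of 14 min SD
#' per endpoint, EEG-device endpoint offsets of 5 min SD quantized to the
#' 30-s epoch grid, and a 5% chance per night that a boundary epoch carries
#' a sensor problem.
#'
#' @param n_subjects,n_nights cohort size (default 10 subjects x 7 nights).
#' @param seed integer seed; all randomness in the simulator flows from it
#'   via fixed per-component offsets.
#' @param bed_mu,rise_mu population mean bed / rise clock times (`"HH:MM"`).
#' @param subject_sd_min between-subject SD of mean bed and rise times (min).
#' @param night_sd_min night-to-night SD within subject (min).
#' @param rater_bias_min named numeric: per-rater systematic offset (min).
#' @param rater_sd_min per-rater random annotation SD (min).
#' @param n_rounds annotation rounds per rater.
#' @param zm_sd_min SD of the EEG device's endpoint offset (min).
#' @param p_boundary_sensor_problem probability a night's first-or-last epoch
#'   is flagged as a sensor problem.
#' @param p_interior_sensor_problem probability of a short interior
#'   sensor-problem run.
#' @param accel_noise_sd white accelerometer noise SD while still (g).
#' @param sample_rate rendered accelerometer rate (Hz).
#' @param start_date first simulated night.
#' @param tz time zone of the simulated clocks.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 10L, n_nights = 7L, seed = 1L,
                       bed_mu = "22:30", rise_mu = "07:00",
                       subject_sd_min = 90, night_sd_min = 30,
                       rater_bias_min = c(rater1 = 3, rater2 = 0, rater3 = -2),
                       rater_sd_min = 14, n_rounds = 2L,
                       zm_sd_min = 5, p_boundary_sensor_problem = 0.05,
                       p_interior_sensor_problem = 0.05,
                       accel_noise_sd = 0.005, sample_rate = 30,
                       start_date = as.Date("2018-10-01"), tz = "UTC") {
  stopifnot(n_subjects >= 1, n_nights >= 1,
            subject_sd_min >= 0, night_sd_min >= 0, rater_sd_min >= 0,
            zm_sd_min >= 0,
            p_boundary_sensor_problem >= 0, p_boundary_sensor_problem <= 1,
            accel_noise_sd >= 0, sample_rate > 0)
  structure(as.list(environment()), class = "sim_config")
}

clock_to_min <- function(x) {
  p <- as.numeric(strsplit(x, ":", fixed = TRUE)[[1L]])
  p[1L] * 60 + p[2L]
}

# per-component substream: deterministic function of the master seed
component_seed <- function(config, offset) {
  (as.integer(config$seed) + offset * 10007L) %% .Machine$integer.max
}

#' Simulate behavior timelines with known in-bed intervals
#'
#' Per subject, nightly to-bed and rise times are drawn around the subject's
#' own means; infeasible nights (rise not after bed) are resampled. Days are
#' filled with contiguous sit / stand / walk / other blocks of 10-90 min.
#'
#' @param config a [sim_config()].
#' @return A list of `behavior_timeline` objects, one per subject, each a
#'   data frame of contiguous segments `(start, end, behavior)` with
#'   attributes `subject_id` and `truth` (the true [inbed_events()]).
#' @export
simulate_timeline <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(component_seed(config, 1L))
  bed_mu <- clock_to_min(config$bed_mu)
  rise_mu <- clock_to_min(config$rise_mu)
  lapply(seq_len(config$n_subjects), function(s) {
    subj <- sprintf("S%02d", s)
    s_bed <- bed_mu + stats::rnorm(1, 0, config$subject_sd_min)
    s_rise <- rise_mu + stats::rnorm(1, 0, config$subject_sd_min / 2)
    to_bed <- out_of_bed <- as.POSIXct(rep(NA_real_, config$n_nights),
                                       tz = config$tz, origin = "1970-01-01")
    for (d in seq_len(config$n_nights)) {
      night <- config$start_date + (d - 1L)
      midnight <- as.POSIXct(paste(night, "00:00:00"), tz = config$tz)
      repeat {
        tb <- midnight + (s_bed + stats::rnorm(1, 0, config$night_sd_min)) * 60
        ob <- midnight + 86400 +
          (s_rise + stats::rnorm(1, 0, config$night_sd_min)) * 60
        if (as.numeric(difftime(ob, tb, units = "hours")) >= 3) break
      }
      to_bed[d] <- tb; out_of_bed[d] <- ob
    }
    truth <- inbed_events(subj, to_bed, out_of_bed, source = "truth",
                          night_id = config$start_date + seq_len(config$n_nights) - 1L)
    segs <- fill_timeline(truth, config)
    structure(segs, subject_id = subj, truth = truth,
              class = c("behavior_timeline", "data.frame"))
  })
}

# contiguous segments covering [first rise-eve, last rise]: in_bed at night,
# random daytime blocks otherwise
fill_timeline <- function(truth, config) {
  day_behaviors <- c("sit", "stand", "walk", "other")
  day_weights <- c(0.45, 0.2, 0.25, 0.1)
  segs <- list()
  span_start <- truth$to_bed[1L] - 3 * 3600  # lead-in before the first night
  cursor <- span_start
  for (i in seq_len(nrow(truth))) {
    while (as.numeric(difftime(truth$to_bed[i], cursor, units = "mins")) > 1e-6) {
      len <- min(stats::runif(1, 10, 90),
                 as.numeric(difftime(truth$to_bed[i], cursor, units = "mins")))
      segs[[length(segs) + 1L]] <- data.frame(
        start = cursor, end = cursor + len * 60,
        behavior = sample(day_behaviors, 1L, prob = day_weights))
      cursor <- cursor + len * 60
    }
    segs[[length(segs) + 1L]] <- data.frame(
      start = truth$to_bed[i], end = truth$out_of_bed[i], behavior = "in_bed")
    cursor <- truth$out_of_bed[i]
  }
  do.call(rbind, segs)
}

#' @export
print.behavior_timeline <- function(x, ...) {
  cat(sprintf("<behavior_timeline> %s: %d segments, %d nights, %s -> %s\n",
              attr(x, "subject_id"), nrow(x), sum(x$behavior == "in_bed"),
              format(x$start[1L], "%Y-%m-%d %H:%M"),
              format(x$end[nrow(x)], "%Y-%m-%d %H:%M")))
  invisible(x)
}

# posture model per (behavior, site): inclination range (deg) and
# longitudinal noise SD (g); chosen so the windowed classifiers fire
POSTURE_TABLE <- list(
  in_bed = list(hip = c(70, 110), thigh = c(80, 100), noise = NA),
  sit    = list(hip = c(5, 25),  thigh = c(80, 100), noise = NA),
  stand  = list(hip = c(0, 10),  thigh = c(0, 10),   noise = NA),
  walk   = list(hip = c(0, 10),  thigh = c(0, 10),   noise = 0.3),
  other  = list(hip = c(40, 60), thigh = c(50, 70),  noise = 0.15)
)

#' Render a behavior timeline as raw accelerometry
#'
#' Gravity-projection synthesis: within each segment a constant segment
#' inclination is drawn from the posture's range, the 1 g gravity vector is
#' projected onto the device axes (x longitudinal, remainder on z), and white
#' noise is added (the configured still-noise SD, or a larger
#' movement-specific SD for walking and other activity). No bout-level
#' autocorrelation is modelled.
#'
#' @param timeline a `behavior_timeline` from [simulate_timeline()].
#' @param site `"hip"` or `"thigh"`.
#' @param config the [sim_config()].
#' @return An [accel_recording()] at `config$sample_rate`.
#' @export
render_accel <- function(timeline, site, config) {
  site <- match.arg(site, c("hip", "thigh"))
  set.seed(component_seed(config, 2L + (site == "thigh")))
  rate <- config$sample_rate
  pieces <- lapply(seq_len(nrow(timeline)), function(i) {
    n <- round(as.numeric(difftime(timeline$end[i], timeline$start[i],
                                   units = "secs")) * rate)
    if (n <= 0) return(NULL)
    p <- POSTURE_TABLE[[timeline$behavior[i]]]
    theta <- stats::runif(1, p[[site]][1], p[[site]][2]) * pi / 180
    noise <- if (is.na(p$noise)) config$accel_noise_sd else p$noise
    cbind(ax = cos(theta) + stats::rnorm(n, 0, noise),
          ay = stats::rnorm(n, 0, noise),
          az = sin(theta) + stats::rnorm(n, 0, noise))
  })
  xyz <- do.call(rbind, pieces)
  accel_recording(site = site, start_time = timeline$start[1L], xyz = xyz,
                  sample_rate = rate)
}

#' Simulate rater annotations of the true in-bed events
#'
#' Each rater / round annotates every night's endpoints as
#' truth + Normal(bias, SD), independently per endpoint and night,
#' emulating a panel of raters labelling the feature WAVs twice.
#'
#' @param true_events an [inbed_events()] data frame of true intervals.
#' @param config the [sim_config()] (rater biases, SD, rounds, seed).
#' @return Named list of [inbed_events()], one per `rater<i>_round<j>`.
#' @export
simulate_raters <- function(true_events, config) {
  set.seed(component_seed(config, 4L))
  out <- list()
  n <- nrow(true_events)
  for (r in seq_along(config$rater_bias_min)) {
    for (rd in seq_len(config$n_rounds)) {
      nm <- sprintf("%s_round%d", names(config$rater_bias_min)[r], rd)
      tb <- true_events$to_bed +
        stats::rnorm(n, config$rater_bias_min[r], config$rater_sd_min) * 60
      ob <- true_events$out_of_bed +
        stats::rnorm(n, config$rater_bias_min[r], config$rater_sd_min) * 60
      out[[nm]] <- inbed_events(true_events$subject_id, tb, ob, source = nm,
                                night_id = true_events$night_id)
    }
  }
  out
}

#' Simulate EEG epoch records for the true in-bed events
#'
#' Endpoints are jittered by Normal(0, `zm_sd_min`) and snapped to the 30-s
#' epoch grid; epochs tile the interval with plausible stage labels (wake at
#' the edges, sleep stages inside). With probability
#' `p_boundary_sensor_problem` the first or last epoch is flagged
#' `SENSOR_PROBLEM` (such nights are discarded downstream); with probability
#' `p_interior_sensor_problem` a short interior run is flagged, which must
#' not move the endpoints.
#'
#' @param true_events an [inbed_events()] data frame.
#' @param config the [sim_config()].
#' @return A data frame in the epoch-CSV schema
#'   (`subject,night,epoch_start,stage`); pass through [as_zm_nights()] /
#'   [zm_events()] to derive events.
#' @export
simulate_zm <- function(true_events, config) {
  set.seed(component_seed(config, 5L))
  rows <- lapply(seq_len(nrow(true_events)), function(i) {
    tb <- true_events$to_bed[i] + stats::rnorm(1, 0, config$zm_sd_min) * 60
    ob <- true_events$out_of_bed[i] + stats::rnorm(1, 0, config$zm_sd_min) * 60
    tb <- round(as.numeric(tb) / ZM_EPOCH_S) * ZM_EPOCH_S
    ob <- round(as.numeric(ob) / ZM_EPOCH_S) * ZM_EPOCH_S
    if (ob <= tb) ob <- tb + ZM_EPOCH_S
    starts <- seq(tb, ob - ZM_EPOCH_S, by = ZM_EPOCH_S)
    n <- length(starts)
    stage <- sample(c("LIGHT", "DEEP", "REM"), n, replace = TRUE,
                    prob = c(0.5, 0.25, 0.25))
    edge <- ceiling(min(n / 10, 10))
    stage[seq_len(edge)] <- "WAKE"
    stage[n - seq_len(edge) + 1L] <- "WAKE"
    if (n > 4L && stats::runif(1) < config$p_interior_sensor_problem) {
      at <- sample(2:(n - 2L), 1L)
      stage[at:min(at + 3L, n - 1L)] <- "SENSOR_PROBLEM"
    }
    if (stats::runif(1) < config$p_boundary_sensor_problem) {
      if (stats::runif(1) < 0.5) stage[1L] <- "SENSOR_PROBLEM"
      else stage[n] <- "SENSOR_PROBLEM"
    }
    data.frame(subject = true_events$subject_id[i],
               night = as.character(true_events$night_id[i]),
               epoch_start = format(as.POSIXct(starts, tz = config$tz,
                                               origin = "1970-01-01"),
                                    "%Y-%m-%dT%H:%M:%S"),
               stage = stage, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate a sleep diary
#'
#' Self-reported bed and rise clock times: truth plus reporting error
#' (Normal with the rater SD, rounded to 5 minutes, the granularity people
#' typically report at).
#'
#' @param true_events an [inbed_events()] data frame.
#' @param config the [sim_config()].
#' @return A data frame in the diary-CSV schema
#'   (`subject,date,to_bed,out_of_bed`).
#' @export
simulate_diary <- function(true_events, config) {
  set.seed(component_seed(config, 6L))
  n <- nrow(true_events)
  jit <- function(ts) {
    t2 <- ts + stats::rnorm(n, 0, config$rater_sd_min) * 60
    t2 <- as.POSIXct(round(as.numeric(t2) / 300) * 300,
                     tz = config$tz, origin = "1970-01-01")
    format(t2, "%H:%M")
  }
  data.frame(subject = true_events$subject_id,
             date = as.character(true_events$night_id),
             to_bed = jit(true_events$to_bed),
             out_of_bed = jit(true_events$out_of_bed),
             stringsAsFactors = FALSE)
}

#' Run the full event-level simulation
#'
#' Generates timelines, true events, rater annotation sets, EEG epoch
#' records and a diary for the configured cohort. Raw accelerometry is not
#' rendered here (it is large); use [render_accel()] per subject when the
#' signal pipeline itself is under study.
#'
#' @param config a [sim_config()].
#' @return A list: `config`, `timelines`, `truth` (all subjects' true
#'   events), `raters` (named list of event sets), `zm` (epoch rows),
#'   `zm_events` (derived, with discards), `diary` (diary rows),
#'   `diary_events`.
#' @export
simulate_study <- function(config = sim_config()) {
  timelines <- simulate_timeline(config)
  truth <- do.call(rbind, lapply(timelines, attr, "truth"))
  class(truth) <- c("inbed_events", "data.frame")
  raters <- simulate_raters(truth, config)
  zm <- simulate_zm(truth, config)
  zm_df <- zm
  zm_df$epoch_start <- parse_iso_time(zm_df$epoch_start, config$tz)
  zmev <- zm_events(as_zm_nights(zm_df))
  diary <- simulate_diary(truth, config)
  diary_path <- tempfile(fileext = ".csv")
  utils::write.csv(diary, diary_path, row.names = FALSE, quote = FALSE)
  diaryev <- parse_diary(diary_path, tz = config$tz)
  unlink(diary_path)
  list(config = config, timelines = timelines, truth = truth,
       raters = raters, zm = zm, zm_events = zmev,
       diary = diary, diary_events = diaryev)
}

#' Write a complete fixture directory
#'
#' Emits the exact file formats the rest of the toolchain consumes: rater
#' label files plus sidecar metadata, the epoch CSV, the diary CSV, a tidy
#' truth events CSV, and optionally rendered two-site accelerometer CSVs for
#' the first `render_subjects` subjects (off by default: raw CSVs are large).
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @param render_subjects how many subjects' raw accelerometry to render.
#' @return The [simulate_study()] result, invisibly.
#' @export
write_fixture_dir <- function(config, dir, render_subjects = 0L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_study(config)
  utils::write.csv(sim$zm, file.path(dir, "zm_epochs.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$diary, file.path(dir, "diary.csv"),
                   row.names = FALSE, quote = FALSE)
  write_events_csv(c(list(truth = sim$truth), sim$raters),
                   file.path(dir, "events.csv"), tz = config$tz)
  for (nm in names(sim$raters)) {
    e <- sim$raters[[nm]]
    for (subj in unique(e$subject_id)) {
      sub <- e[e$subject_id == subj, ]
      rec_start <- min(sim$truth$to_bed[sim$truth$subject_id == subj]) - 3 * 3600
      write_label_file(events_to_labels(sub, rec_start),
                       file.path(dir, sprintf("%s_%s.txt", subj, nm)))
    }
  }
  for (s in seq_len(min(render_subjects, config$n_subjects))) {
    tl <- sim$timelines[[s]]
    subj <- attr(tl, "subject_id")
    for (site in c("hip", "thigh")) {
      write_accel_csv(render_accel(tl, site, config),
                      file.path(dir, sprintf("%s_%s.csv", subj, site)))
    }
  }
  invisible(sim)
}
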