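# Small in-code fixtures shared across tests.

T0 <- as.POSIXct("2018-10-01 20:00:00", tz = "UTC")

# constant-orientation recording: `vec` repeated for `secs` seconds
const_recording <- function(site, vec, secs, rate = 30, start = T0) {
  n <- secs * rate
  accel_recording(site, start,
                  matrix(rep(vec, each = n), ncol = 3), sample_rate = rate)
}

# recording whose x axis follows a linear ramp a + b*t (y = z = 0 is
# avoided by a tiny constant z so inclination stays defined)
ramp_recording <- function(site, a, b, secs, rate = 50, start = T0) {
  t <- seq(0, by = 1 / rate, length.out = secs * rate)
  accel_recording(site, start, cbind(a + b * t, 0, 0.01),
                  sample_rate = rate, time = t)
}

write_accel_fixture <- function(path, times, ax, ay = 0, az = 0) {
  df <- data.frame(timestamp = format(times + 5e-4, "%Y-%m-%dT%H:%M:%OS3"),
                   ax = ax, ay = rep_len(ay, length(ax)),
                   az = rep_len(az, length(ax)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# one ZM night from a stage vector, 30-s epochs from `start`
zm_night_from_stages <- function(stages, start = as.POSIXct("2018-10-01 23:00:00", tz = "UTC"),
                                 subject = "S01", night = as.Date("2018-10-01")) {
  df <- data.frame(subject = subject, night = as.character(night),
                   epoch_start = start + 30 * (seq_along(stages) - 1L),
                   stage = stages, stringsAsFactors = FALSE)
  as_zm_nights(df)[[1L]]
}

random_feature_series <- function(n, seed = 1, start = T0) {
  set.seed(seed)
  ch <- cbind(sample(c(-1, 1), n, TRUE),
              sample(c(-1, 0, 1), n, TRUE),
              sample(seq(-1, 1, by = 0.4), n, TRUE),
              runif(n, -1, 1), runif(n, 0, 1),
              runif(n, -1, 1), runif(n, 0, 1))
  feature_series(start, ch)
}
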