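test_that("windowing yields floor((N-60)/30)+1 frames with 1-s centers", {
  rec300 <- accel_recording("hip", T0, matrix(rnorm(900, 0, 0.01) + c(1, 0, 0)[rep(1:3, each = 300)],
                                              ncol = 3), sample_rate = 30)
  wins <- frame_windows(rec300)
  expect_length(wins, 9L)
  centers <- vapply(wins, function(w) as.numeric(attr(w, "center_time")), 0)
  expect_equal(diff(centers), rep(1, 8))
  expect_equal(centers[1], as.numeric(T0) + 1)

  expect_length(frame_windows(const_recording("hip", c(1, 0, 0), secs = 2)), 1L)
  rec59 <- accel_recording("hip", T0, matrix(1, 59, 3), sample_rate = 30)
  expect_length(frame_windows(rec59), 0L)

  for (n in c(0, 1, 59, 60, 61, 89, 90, 91, 150, 300, 301, 7200)) {
    expect_identical(actibed:::n_frames(n),
                     if (n < 60) 0L else as.integer(floor((n - 60) / 30) + 1))
  }
})

test_that("inclination matches the axis geometry and is scale invariant", {
  w <- function(v) matrix(rep(v, each = 60), ncol = 3)
  expect_equal(inclination_deg(w(c(1, 0, 0))), 0)
  expect_equal(inclination_deg(w(c(0, 1, 0))), 90)
  expect_equal(inclination_deg(w(c(-1, 0, 0))), 180)
  expect_equal(inclination_deg(w(c(0, 0, 1))), 90)
  expect_true(is.na(inclination_deg(w(c(0, 0, 0)))))

  set.seed(11)
  for (i in 1:20) {
    win <- matrix(rnorm(180), ncol = 3)
    base <- inclination_deg(win)
    for (s in c(0.1, 2, 117)) {
      expect_equal(inclination_deg(win * s), base, tolerance = 1e-9)
    }
  }
})

test_that("longitudinal SD is the population SD of the x axis", {
  expect_equal(sd_longitudinal(matrix(rep(c(0.4, 0, 0.9), each = 60), ncol = 3)), 0)
  alt <- matrix(c(rep(c(0.1, -0.1), 30), rep(0, 120)), ncol = 3)
  expect_equal(sd_longitudinal(alt), 0.1)
  set.seed(5)
  win <- matrix(rnorm(180, 0, 0.3), ncol = 3)
  x <- win[, 1]
  two_pass <- sqrt(sum((x - mean(x))^2) / length(x))  # direct formula
  expect_equal(sd_longitudinal(win), two_pass, tolerance = 1e-12)
})

test_that("activity classification follows the inclination/SD decision rule", {
  expect_identical(classify_activity(90, 0.005, 0.005), 0L)   # sitting
  expect_identical(classify_activity(10, 0.005, 0.005), 1L)   # standing
  expect_identical(classify_activity(10, 0.300, 0.250), 1L)   # moving/walking
  expect_identical(classify_activity(90, 0.300, 0.250), -1L)  # other
  expect_identical(classify_activity(45, 0.5, 0.5), 1L)       # boundary: upright
  expect_identical(classify_activity(45 + 1e-9, 0.1, 0), 0L)  # boundary: sd at s_move
})

test_that("lying requires hip inclination strictly above 65 and concurrent sitting", {
  expect_true(classify_lying(70, 0L))
  expect_false(classify_lying(60, 0L))
  expect_false(classify_lying(70, 1L))
  expect_false(classify_lying(70, -1L))
  expect_false(classify_lying(65, 0L))                 # strict inequality
  expect_true(classify_lying(65 + 1e-12, 0L))
})

test_that("the lying decision flips exactly above 65 degrees in a sweep", {
  angles <- 0:180
  lying <- classify_lying(angles, rep(0L, length(angles)))
  expect_identical(max(angles[!lying]), 65L)
  expect_identical(min(angles[lying]), 66L)
  eps_up <- 65 * (1 + .Machine$double.eps)
  expect_false(classify_lying(65, 0L))
  expect_true(classify_lying(eps_up, 0L))
})

test_that("time-of-day bins map local clock to six evenly spaced levels", {
  d <- function(h, m = 0) as.POSIXct(sprintf("2018-10-01 %02d:%02d:00", h, m), tz = "UTC")
  expect_equal(time_bin_level(d(2)), -1)
  expect_equal(time_bin_level(d(0)), -1)
  expect_equal(time_bin_level(d(4)), -0.6)     # left-closed boundary
  expect_equal(time_bin_level(d(3, 59)), -1)
  expect_equal(time_bin_level(d(23, 59)), 1)
  expect_equal(time_bin_level(d(12)), 0.2)
  expect_equal(time_bin_level(c(d(6), d(10), d(17), d(21))),
               c(-0.6, -0.2, 0.6, 1))
})

test_that("encoding maps each channel kind into [-1, 1] as documented", {
  expect_equal(encode_feature(0, "inclination"), 0)
  expect_equal(encode_feature(180, "inclination"), 1)
  expect_equal(encode_feature(90, "inclination"), 0.5)
  expect_equal(encode_feature(0, "sd"), -1)
  expect_equal(encode_feature(0.25, "sd"), 0)
  expect_equal(encode_feature(0.5, "sd"), 1)
  expect_equal(encode_feature(3, "sd"), 1)              # saturates
  expect_equal(encode_feature(c(TRUE, FALSE), "lying"), c(1, -1))
  expect_equal(encode_feature(c(-1L, 0L, 1L), "activity"), c(-1, 0, 1))
  expect_error(encode_feature(190, "inclination"), "0, 180")
  expect_error(encode_feature(-0.1, "sd"), "non-negative")
  expect_error(encode_feature(2L, "activity"), "-1, 0 or \\+1")
})

test_that("a 60-s two-site pair yields 59 frames spaced one second apart", {
  hip <- const_recording("hip", c(0, 1, 0), secs = 60)
  thigh <- const_recording("thigh", c(0, 0, 1), secs = 60)
  f <- build_features(hip, thigh)
  expect_equal(nrow(f$channels), 59L)
  expect_equal(f$rate, 1)
  expect_equal(as.numeric(f$start_time), as.numeric(T0) + 1)
})

test_that("a flat hip with a still horizontal thigh is lying throughout", {
  hip <- const_recording("hip", c(0, 1, 0), secs = 60)       # 90 deg
  thigh <- const_recording("thigh", c(0, 0, 1), secs = 60)   # 90 deg, still
  f <- build_features(hip, thigh)
  expect_true(all(f$channels[, "Lying"] == 1))
  expect_true(all(f$channels[, "Activity"] == 0))
  expect_equal(unique(f$channels[, "Hip-Inclination"]), 0.5)
})

test_that("an upright posture is never lying", {
  hip <- const_recording("hip", c(1, 0, 0), secs = 60)
  thigh <- const_recording("thigh", c(1, 0, 0), secs = 60)
  f <- build_features(hip, thigh)
  expect_true(all(f$channels[, "Lying"] == -1))
  expect_true(all(f$channels[, "Activity"] == 1))
})

test_that("non-overlapping recordings are rejected", {
  hip <- const_recording("hip", c(1, 0, 0), secs = 10, start = T0)
  thigh <- const_recording("thigh", c(1, 0, 0), secs = 10, start = T0 + 3600)
  expect_error(build_features(hip, thigh), "overlap")
})

test_that("every emitted channel value lies in [-1, 1] on randomized input", {
  set.seed(99)
  for (i in 1:5) {
    hip <- accel_recording("hip", T0, matrix(rnorm(3 * 900, 0, 1), ncol = 3),
                           sample_rate = 30)
    thigh <- accel_recording("thigh", T0, matrix(rnorm(3 * 900, 0, 1), ncol = 3),
                             sample_rate = 30)
    f <- build_features(hip, thigh)
    vals <- f$channels[!f$missing, ]
    expect_true(all(vals >= -1 & vals <= 1))
    # lying implies concurrently sitting
    expect_true(all(f$channels[f$channels[, "Lying"] == 1 & !f$missing, "Activity"] == 0))
  }
})

test_that("the feature pipeline is deterministic", {
  set.seed(3)
  hx <- matrix(rnorm(2700, 0, 0.5), ncol = 3)
  tx <- matrix(rnorm(2700, 0, 0.5), ncol = 3)
  hip <- accel_recording("hip", T0, hx, sample_rate = 30)
  thigh <- accel_recording("thigh", T0, tx, sample_rate = 30)
  f1 <- build_features(hip, thigh)
  f2 <- build_features(hip, thigh)
  expect_identical(f1$channels, f2$channels)
  expect_identical(f1$missing, f2$missing)
})

test_that("frames overlapping a recording gap are marked missing", {
  gap <- data.frame(start = 20, end = 25)
  hip <- accel_recording("hip", T0, matrix(rep(c(0, 1, 0), each = 1800), ncol = 3),
                         sample_rate = 30, gaps = gap)
  thigh <- const_recording("thigh", c(0, 0, 1), secs = 60)
  f <- build_features(hip, thigh)
  expect_true(any(f$missing))
  expect_true(all(is.na(f$channels[f$missing, ])))
  # frames fully clear of the gap stay valid
  expect_false(f$missing[5])
  expect_true(f$missing[21])
})
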