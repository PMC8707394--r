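test_that("the simulator is deterministic under its seed", {
  cfg <- sim_config(n_subjects = 2, n_nights = 3, seed = 77)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$raters, s2$raters)
  expect_identical(s1$zm, s2$zm)
  expect_identical(s1$diary, s2$diary)
})

test_that("each subject gets exactly n_nights in-bed segments", {
  cfg <- sim_config(n_subjects = 3, n_nights = 7, seed = 5)
  tls <- simulate_timeline(cfg)
  for (tl in tls) {
    expect_equal(sum(tl$behavior == "in_bed"), 7L)
    # segments are contiguous and non-overlapping
    expect_true(all(abs(as.numeric(tl$start[-1]) -
                          as.numeric(tl$end[-nrow(tl)])) < 1e-6))
  }
})

test_that("zero schedule variance gives identical clock times every night", {
  cfg <- sim_config(n_subjects = 1, n_nights = 5, seed = 9,
                    subject_sd_min = 0, night_sd_min = 0)
  truth <- attr(simulate_timeline(cfg)[[1]], "truth")
  expect_equal(length(unique(format(truth$to_bed, "%H:%M:%S"))), 1L)
  expect_equal(length(unique(format(truth$out_of_bed, "%H:%M:%S"))), 1L)
  expect_equal(format(truth$to_bed[1], "%H:%M"), "22:30")
})

test_that("noise-free raters reproduce the truth and biased raters shift by it", {
  cfg0 <- sim_config(n_subjects = 2, n_nights = 3, seed = 3,
                     rater_bias_min = c(rater1 = 0), rater_sd_min = 0,
                     n_rounds = 1L)
  truth <- attr(simulate_timeline(cfg0)[[1]], "truth")
  ann <- simulate_raters(truth, cfg0)$rater1_round1
  expect_equal(as.numeric(ann$to_bed), as.numeric(truth$to_bed))
  expect_equal(as.numeric(ann$out_of_bed), as.numeric(truth$out_of_bed))

  # long-run mean offset approaches the injected +3 min bias
  cfg3 <- sim_config(n_subjects = 30, n_nights = 7, seed = 4,
                     rater_bias_min = c(rater1 = 3), rater_sd_min = 14,
                     n_rounds = 1L)
  sim <- simulate_study(cfg3)
  ann <- sim$raters$rater1_round1
  off <- as.numeric(difftime(ann$to_bed, sim$truth$to_bed, units = "mins"))
  # mean of 210 draws with SD 14: standard error ~1 min, allow 3 SE
  expect_lt(abs(mean(off) - 3), 3)
})

test_that("boundary sensor-problem probability drives downstream discards", {
  base <- list(n_subjects = 3, n_nights = 4, seed = 12)
  cfg0 <- do.call(sim_config, c(base, list(p_boundary_sensor_problem = 0,
                                           p_interior_sensor_problem = 0)))
  sim0 <- simulate_study(cfg0)
  expect_equal(nrow(attr(sim0$zm_events, "discarded")), 0L)
  expect_equal(nrow(sim0$zm_events), 12L)

  cfg1 <- do.call(sim_config, c(base, list(p_boundary_sensor_problem = 1)))
  sim1 <- simulate_study(cfg1)
  expect_equal(nrow(sim1$zm_events), 0L)
  expect_equal(nrow(attr(sim1$zm_events, "discarded")), 12L)
})

test_that("with no EEG jitter derived events equal truth to 30-s quantization", {
  cfg <- sim_config(n_subjects = 2, n_nights = 3, seed = 6, zm_sd_min = 0,
                    p_boundary_sensor_problem = 0, p_interior_sensor_problem = 0)
  sim <- simulate_study(cfg)
  p_tb <- as.numeric(sim$zm_events$to_bed) - as.numeric(sim$truth$to_bed)
  p_ob <- as.numeric(sim$zm_events$out_of_bed) - as.numeric(sim$truth$out_of_bed)
  expect_true(all(abs(p_tb) <= 15))
  expect_true(all(abs(p_ob) <= 15))
})

test_that("rendered postures reproduce their intended classes on interior frames", {
  cfg <- sim_config(seed = 8, accel_noise_sd = 0.005)
  start <- as.POSIXct("2018-10-01 12:00:00", tz = "UTC")
  tl <- data.frame(start = start + c(0, 3600, 7200),
                   end = start + c(3600, 7200, 10800),
                   behavior = c("in_bed", "walk", "sit"))
  hip <- render_accel(tl, "hip", cfg)
  thigh <- render_accel(tl, "thigh", cfg)
  f <- build_features(hip, thigh)
  seg <- function(from_s, to_s) {
    t_off <- as.numeric(f$start_time) - as.numeric(start) + seq_len(length(f)) - 1
    which(t_off > from_s + 60 & t_off < to_s - 60)  # segment interior
  }
  lying <- f$channels[, "Lying"]; act <- f$channels[, "Activity"]
  expect_gt(mean(lying[seg(0, 3600)] == 1), 0.95)
  expect_gt(mean(act[seg(3600, 7200)] == 1), 0.95)
  expect_gt(mean(lying[seg(3600, 7200)] == -1), 0.95)
  expect_gt(mean(act[seg(7200, 10800)] == 0), 0.95)
  expect_gt(mean(lying[seg(7200, 10800)] == -1), 0.95)
})

test_that("noiseless rendering classifies every interior frame correctly", {
  cfg <- sim_config(seed = 15, accel_noise_sd = 0)
  start <- as.POSIXct("2018-10-01 12:00:00", tz = "UTC")
  tl <- data.frame(start = start + c(0, 1800), end = start + c(1800, 3600),
                   behavior = c("sit", "in_bed"))
  f <- build_features(render_accel(tl, "hip", cfg),
                      render_accel(tl, "thigh", cfg))
  t_off <- as.numeric(f$start_time) - as.numeric(start) + seq_len(length(f)) - 1
  sit_i <- t_off > 2 & t_off < 1798
  bed_i <- t_off > 1802 & t_off < 3598
  expect_true(all(f$channels[sit_i, "Lying"] == -1))
  expect_true(all(f$channels[sit_i, "Activity"] == 0))
  expect_true(all(f$channels[bed_i, "Lying"] == 1))
})

test_that("the full signal pipeline recovers true in-bed intervals within 2 min", {
  cfg <- sim_config(n_subjects = 1, n_nights = 1, seed = 10,
                    accel_noise_sd = 0)
  tl <- simulate_timeline(cfg)[[1]]
  truth <- attr(tl, "truth")
  hip <- render_accel(tl, "hip", cfg)
  thigh <- render_accel(tl, "thigh", cfg)
  f <- build_features(hip, thigh)
  track <- propose_inbed_labels(f)
  expect_equal(nrow(track), 1L)
  ev <- labels_to_events(track, f$start_time, "S01", source = "auto")
  expect_lt(abs(as.numeric(difftime(ev$to_bed, truth$to_bed, units = "mins"))), 2)
  expect_lt(abs(as.numeric(difftime(ev$out_of_bed, truth$out_of_bed, units = "mins"))), 2)
})

test_that("the fixture directory contains every consumable format", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_subjects = 2, n_nights = 2, seed = 20)
  sim <- write_fixture_dir(cfg, dir)
  expect_true(file.exists(file.path(dir, "zm_epochs.csv")))
  expect_true(file.exists(file.path(dir, "diary.csv")))
  expect_true(file.exists(file.path(dir, "events.csv")))
  labels <- list.files(dir, pattern = "_rater.*\\.txt$")
  expect_length(labels, 2 * length(sim$raters))
  # files parse back through the standard readers
  nights <- parse_zm_csv(file.path(dir, "zm_epochs.csv"))
  expect_gt(length(nights), 0L)
  ev <- read_events_csv(file.path(dir, "events.csv"))
  expect_true("truth" %in% names(ev))
  tr <- read_label_file(file.path(dir, labels[1]))
  expect_equal(nrow(tr), 2L)
})
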