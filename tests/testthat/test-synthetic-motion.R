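test_that("squat truth has exactly n_cycles troughs in the thigh x angle", {
  truth <- generate_motion_truth("squat", n_cycles = 8, cycle_period = 3, seed = 1)
  x <- truth$euler$thigh[, "x"]
  # independent scan: strict local minima deeper than the signal midline
  n <- length(x)
  is_min <- x[2:(n - 1)] < x[1:(n - 2)] & x[2:(n - 1)] < x[3:n]
  deep <- x[2:(n - 1)] < mean(range(x))
  expect_equal(sum(is_min & deep), 8)
})

test_that("generator rejects degenerate inputs", {
  expect_error(generate_motion_truth("squat", amplitude_scale = 0),
               class = "imuagree_degenerate")
  expect_error(generate_motion_truth("squat", n_cycles = 2),
               class = "imuagree_precondition")
  expect_error(generate_motion_truth("moonwalk"))
})

test_that("generation is deterministic given the seed", {
  t1 <- generate_motion_truth("walk", seed = 11)
  t2 <- generate_motion_truth("walk", seed = 11)
  t3 <- generate_motion_truth("walk", seed = 12)
  expect_identical(t1$euler, t2$euler)
  expect_identical(t1$acc, t2$acc)
  expect_false(identical(t1$euler, t3$euler))
})

test_that("walk truth reverses direction at the midpoint", {
  truth <- generate_motion_truth("walk", n_cycles = 10, seed = 2)
  expect_setequal(unique(truth$direction), c(1, -1))
  flips <- which(diff(truth$direction) != 0)
  expect_equal(length(flips), 1)
  # reversal at the midpoint cycle boundary
  expect_equal(truth$time[flips + 1] / truth$cycle_period, 5, tolerance = 0.02)
})

test_that("jump acceleration carries a high-frequency landing transient", {
  jump <- generate_motion_truth("jump", seed = 3)
  squat <- generate_motion_truth("squat", seed = 3)
  hf_power <- function(x, fs = 60) {
    sp <- Mod(stats::fft(x - mean(x)))^2
    f <- (seq_along(x) - 1) / length(x) * fs
    sum(sp[f > 8 & f < 30]) / sum(sp[f > 0 & f < 30])
  }
  expect_gt(hf_power(jump$acc$shank[, "z"]), 5 * hf_power(squat$acc$shank[, "z"]))
})

test_that("identity distortion reproduces the truth exactly", {
  truth <- generate_motion_truth("squat", seed = 5)
  rec <- render_sensor_view(truth, "thigh", sensor_distortion(), seed = 1)
  eul <- quat_to_euler_zxy(rec$quat)
  expect_lt(max(abs(eul - truth$euler$thigh)), 1e-9)
  expect_lt(max(abs(rec$free_acc - truth$acc$thigh)), 1e-9)
})

test_that("offset distortion shifts accelerations by a constant", {
  truth <- generate_motion_truth("squat", seed = 5)
  rec <- render_sensor_view(truth, "shank",
                            sensor_distortion(offset = 5), seed = 1)
  d <- rec$free_acc - truth$acc$shank
  expect_equal(range(d), c(5, 5), tolerance = 1e-9)
})

test_that("lag must be shorter than the signal and shifts samples", {
  truth <- generate_motion_truth("squat", seed = 5)
  expect_error(render_sensor_view(truth, "thigh",
                                  sensor_distortion(lag = truth$n)),
               class = "imuagree_precondition")
  rec <- render_sensor_view(truth, "thigh", sensor_distortion(lag = 5), seed = 1)
  expect_equal(rec$free_acc[6:100, ], truth$acc$thigh[1:95, ],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("increasing noise never increases the median waveform r2", {
  truth <- generate_motion_truth("squat", seed = 9)
  cfg <- pipeline_config()
  r2_at <- function(sd) {
    r2 <- vapply(1:6, function(r) {
      crit <- render_sensor_view(truth, "shank",
                                 meta = list(device = "criterion"), seed = 50 + r)
      test <- render_sensor_view(truth, "shank", sensor_distortion(noise_sd = sd),
                                 seed = 150 + r)
      thigh <- render_sensor_view(truth, "thigh", seed = 250)
      out_t <- imuagree:::process_device_trial(list(thigh = thigh, shank = test), cfg)
      out_c <- imuagree:::process_device_trial(list(thigh = thigh, shank = crit), cfg)
      lfm_participant(out_t$cycles[["shank|acc|z"]],
                      out_c$cycles[["shank|acc|z"]])$r2
    }, numeric(1))
    stats::median(r2)
  }
  meds <- vapply(c(0, 0.3, 1, 3), r2_at, numeric(1))
  expect_true(all(diff(meds) <= 1e-10))
})

test_that("cohort outcome draws follow the variance-components identity", {
  # no within-subject variance: ICC exactly 1
  co <- generate_cohort(cohort_spec(20, var_between = 1, var_within = 0,
                                    seed = 21), "squat", n_sessions = 2,
                        devices = "test")
  pr <- process_cohort(co, devices = "test")
  rel <- run_reliability(pr, c(1, 2))
  expect_true(all(abs(rel$cases$icc - 1) < 1e-6))

  # no between-subject variance: ICC near 0 in expectation
  est <- vapply(1:200, function(r) {
    m <- sample_cohort_outcomes(cohort_spec(30, var_between = 0, var_within = 1,
                                            seed = 1000 + r), k_sessions = 2)
    icc_consistency(m)$icc
  }, numeric(1))
  expect_lt(abs(mean(est)), 0.05)

  # var 3 / 1 recovers ICC 0.75 over replicates
  est <- vapply(1:300, function(r) {
    m <- sample_cohort_outcomes(cohort_spec(200, var_between = 3, var_within = 1,
                                            seed = 3000 + r), k_sessions = 2)
    icc_consistency(m)$icc
  }, numeric(1))
  expect_equal(mean(est), 0.75, tolerance = 0.03)
})

test_that("full-pipeline range outcomes inherit the amplitude multipliers", {
  # ranges measured through filtering/segmentation must be proportional to
  # the injected per-session amplitude multiplier, which is what ties the
  # outcome-level variance-components model to the signal pipeline
  co <- generate_cohort(cohort_spec(4, var_between = 4, var_within = 1,
                                    seed = 31), "squat", n_sessions = 2,
                        devices = "test")
  pr <- process_cohort(co, devices = "test")
  rt <- pr$range_table
  sub <- rt[rt$location == "thigh" & rt$quantity == "ori" & rt$axis == "x", ]
  measured <- matrix(sub$range_value[order(sub$participant, sub$session)],
                     ncol = 2, byrow = TRUE)
  ratio <- measured / co$multipliers
  expect_lt(stats::sd(ratio) / mean(ratio), 0.02)
})

test_that("cohort generation on disk is complete and deterministic", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  spec <- cohort_spec(2, seed = 77)
  generate_cohort(spec, "squat", n_sessions = 2, dir = dir1)
  generate_cohort(spec, "squat", n_sessions = 2, dir = dir2)
  f1 <- list.files(dir1); f2 <- list.files(dir2)
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(readLines(file.path(dir1, f)), readLines(file.path(dir2, f)))
  }
  # pre-existing target files are a conflict
  expect_error(generate_cohort(spec, "squat", n_sessions = 2, dir = dir1),
               class = "imuagree_io")
})
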