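test_that("identity rows read back as an all-zero recording", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "time,quat_w,quat_x,quat_y,quat_z,freeacc_z,freeacc_x,freeacc_y",
    "0,1,0,0,0,0,0,0",
    "0.0166667,1,0,0,0,0,0,0",
    "0.0333333,1,0,0,0,0,0,0"
  ), path)
  rec <- read_recording(path, list(participant = "P01", device = "test",
                                   location = "sacrum", session = 1,
                                   activity = "squat", sample_rate = 60))
  expect_equal(nrow(rec$quat), 3)
  expect_true(all(rec$free_acc == 0))
  expect_equal(rec$quat[, 1], rep(1, 3))
})

test_that("missing and malformed columns raise named errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  meta <- list(participant = "P01", device = "test", location = "sacrum",
               session = 1, activity = "squat", sample_rate = 60)
  writeLines(c("time,quat_x,quat_y,quat_z,freeacc_z,freeacc_x,freeacc_y",
               "0,0,0,0,0,0,0"), path)
  expect_error(read_recording(path, meta), "quat_w", class = "imuagree_format")

  writeLines(c("time,quat_w,quat_x,quat_y,quat_z,freeacc_z,freeacc_x,freeacc_y",
               "0,1,0,0,0,0,0,0", "0.016,1,0,0,0,NaN,0,0"), path)
  expect_error(read_recording(path, meta), "row 2", class = "imuagree_parse")

  # norm off by > 1e-3 is an integrity error; <= 1e-3 is renormalized
  writeLines(c("time,quat_w,quat_x,quat_y,quat_z,freeacc_z,freeacc_x,freeacc_y",
               "0,1.1,0,0,0,0,0,0", "0.016,1,0,0,0,0,0,0"), path)
  expect_error(read_recording(path, meta), class = "imuagree_integrity")

  writeLines(c("time,quat_w,quat_x,quat_y,quat_z,freeacc_z,freeacc_x,freeacc_y",
               "0,1.0005,0,0,0,0,0,0", "0.016,1,0,0,0,0,0,0"), path)
  rec <- read_recording(path, meta)
  expect_equal(sqrt(sum(rec$quat[1, ]^2)), 1, tolerance = 1e-12)
})

test_that("write/read round trip preserves recordings to 1e-9", {
  for (seed in c(7, 8)) {
    rec <- random_recording(n = 40, seed = seed)
    path <- withr::local_tempfile(fileext = ".csv")
    write_recording(rec, path)
    back <- read_recording(path, list(participant = rec$participant,
                                      device = rec$device,
                                      location = rec$location,
                                      session = rec$session,
                                      activity = rec$activity,
                                      sample_rate = rec$sample_rate))
    expect_lt(max(abs(back$quat - rec$quat)), 1e-9)
    expect_lt(max(abs(back$free_acc - rec$free_acc)), 1e-9)
  }
})

test_that("walking recordings round-trip their direction flags", {
  n <- 30
  rec <- sensor_recording("P02", "test", "shank", 1, "walk",
                          quat = cbind(rep(1, n), 0, 0, 0),
                          free_acc = matrix(seq_len(3 * n) / 10, n, 3),
                          walk_direction = rep(c(1, -1), each = n / 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path)
  back <- read_recording(path, list(participant = "P02", device = "test",
                                    location = "shank", session = 1,
                                    activity = "walk", sample_rate = 60))
  expect_equal(back$walk_direction, rec$walk_direction)
})

test_that("degenerate recordings are rejected at construction", {
  expect_error(sensor_recording("P01", "test", "sacrum", 1, "squat",
                                quat = matrix(c(1, 0, 0, 0), 1, 4),
                                free_acc = matrix(0, 1, 3)),
               class = "imuagree_precondition")
  # walk_direction present iff walking
  expect_error(sensor_recording("P01", "test", "sacrum", 1, "squat",
                                quat = cbind(c(1, 1), 0, 0, 0),
                                free_acc = matrix(0, 2, 3),
                                walk_direction = c(1, 1)),
               class = "imuagree_precondition")
  expect_error(sensor_recording("P01", "test", "sacrum", 1, "walk",
                                quat = cbind(c(1, 1), 0, 0, 0),
                                free_acc = matrix(0, 2, 3)),
               class = "imuagree_precondition")
})

test_that("long-table writer emits fixed schema and round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  empty <- data.frame(participant = character(0), device = character(0),
                      session = integer(0), activity = character(0),
                      location = character(0), quantity = character(0),
                      axis = character(0), range_value = numeric(0),
                      n_cycles_used = integer(0))
  write_long_table(empty, path)
  expect_equal(length(readLines(path)), 1L)  # header only

  rows <- data.frame(participant = c("P01", "P02"), device = "test",
                     session = 1L, activity = "squat", location = "thigh",
                     quantity = "acc", axis = c("z", "x"),
                     range_value = c(1.23456789012, 2.5),
                     n_cycles_used = c(6L, 6L))
  write_long_table(rows, path)
  expect_equal(readLines(path)[1],
               "participant,device,session,activity,location,quantity,axis,range_value,n_cycles_used")
  back <- read_long_table(path)
  expect_equal(back$range_value, rows$range_value, tolerance = 1e-12)
  expect_equal(back$participant, rows$participant)

  bad <- rows; bad$extra <- 1
  expect_error(write_long_table(bad, path), class = "imuagree_format")
})

test_that("manifest round-trips and enforces key uniqueness and file existence", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(cohort_spec(2, seed = 3), "walk", n_sessions = 1,
                        dir = dir)
  man <- read_manifest(file.path(dir, "manifest.yaml"))
  expect_equal(nrow(man$trials), 2 * 1 * 1 * 2 * 3)
  expect_true(all(file.exists(man$trials$path)))
  expect_true(length(man$direction_spans) > 0)

  # duplicate keys rejected
  m2 <- man
  m2$trials <- rbind(m2$trials, m2$trials[1, ])
  m2$trials$path <- basename(m2$trials$path)
  p2 <- file.path(dir, "dup.yaml")
  write_manifest(m2, p2)
  expect_error(read_manifest(p2), class = "imuagree_integrity")

  # missing file rejected
  file.remove(man$trials$path[1])
  expect_error(read_manifest(file.path(dir, "manifest.yaml")),
               class = "imuagree_io")
})
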