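test_that("read_gaze round-trips a well-formed table and honours validity", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(
    time = c(0, 8.333, 16.667),
    left_x = c(100, 101, 102), left_y = c(200, 200, 201),
    right_x = c(102, 103, 104), right_y = c(198, 199, 199),
    left_valid = c(1, 1, 1), right_valid = c(1, 1, 1),
    pupil_left = c(600, 601, 602), pupil_right = c(599, 600, 601)
  )
  write.csv(df, path, row.names = FALSE)
  rec <- read_gaze(path, default_schema(), sampling_rate = 120)
  expect_s3_class(rec, "gaze_recording")
  expect_identical(nrow(rec$samples), 3L)
  expect_true(all(rec$samples$left_valid))
  expect_true(all(rec$samples$right_valid))
  expect_equal(rec$samples$left_x, df$left_x)

  # read -> write -> read is a fixed point
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_gaze(rec, path2)
  rec2 <- read_gaze(path2, default_schema(), sampling_rate = 120)
  expect_equal(rec2$samples, rec$samples)
})

test_that("empty right-eye columns give right_valid all false", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "time,left_x,left_y,right_x,right_y",
    "0,100,200,,", "10,101,200,,", "20,102,201,,"
  ), path)
  rec <- read_gaze(path, list(time = "time", left_x = "left_x",
                              left_y = "left_y", right_x = "right_x",
                              right_y = "right_y"), sampling_rate = 100)
  expect_false(any(rec$samples$right_valid))
  expect_true(all(rec$samples$left_valid))
})

test_that("validity flag overrides stored coordinates (availability mask)", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(time = c(0, 10, 20),
                   left_x = c(1, 2, 3), left_y = c(1, 1, 1),
                   right_x = c(1, 2, 3), right_y = c(1, 1, 1),
                   left_valid = c(1, 0, 1), right_valid = c(1, 1, 0))
  write.csv(df, path, row.names = FALSE)
  sch <- default_schema()[c("time", "left_x", "left_y", "right_x",
                            "right_y", "left_valid", "right_valid")]
  rec <- read_gaze(path, sch, sampling_rate = 100)
  expect_identical(rec$samples$left_valid, c(TRUE, FALSE, TRUE))
  expect_true(is.na(rec$samples$left_x[2]))
  # downstream availability equals the validity mask (both eyes policy)
  tr <- combine_eyes(rec, include_single_eye = FALSE)
  expect_identical(tr$available,
                   rec$samples$left_valid & rec$samples$right_valid)
  tr1 <- combine_eyes(rec, include_single_eye = TRUE)
  expect_identical(tr1$available,
                   rec$samples$left_valid | rec$samples$right_valid)
})

test_that("unparseable coordinates become missing, sentinels mappable", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "time,left_x,left_y,right_x,right_y",
    "0,100,200,-1,-1", "10,oops,200,101,201", "20,102,201,103,199"
  ), path)
  sch <- list(time = "time", left_x = "left_x", left_y = "left_y",
              right_x = "right_x", right_y = "right_y")
  expect_message(
    rec <- read_gaze(path, sch, sampling_rate = 100, na_values = -1),
    "unparseable"
  )
  expect_identical(attr(rec, "n_unparseable"), 1L)
  expect_false(rec$samples$left_valid[2])   # unparseable cell
  expect_false(rec$samples$right_valid[1])  # sentinel -1 mapped to missing
})

test_that("reader rejects malformed inputs with typed errors", {
  sch <- list(time = "time", left_x = "x", left_y = "y")
  expect_error(read_gaze("no/such/file.csv", sch, 120), "missing_file")

  p1 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,x,y", "10,1,1", "5,2,2"), p1)
  expect_error(read_gaze(p1, sch, 120), "timestamps")

  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("time,x,y", p2)
  expect_error(read_gaze(p2, sch, 120), "empty")

  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,a,b", "0,1,1", "10,2,2"), p3)
  expect_error(read_gaze(p3, sch, 120), "not in file")
  expect_error(read_gaze(p3, list(time = "t"), 120), "at least one eye")
})

test_that("fixation tables serialize and round-trip", {
  # empty set -> header-only file
  p <- withr::local_tempfile(fileext = ".csv")
  write_fixations(as_empty <- data.frame(), p)
  expect_identical(nrow(read_fixations(p)), 0L)
  expect_identical(length(readLines(p)), 1L)

  # one fixation [0, 200) -> one row, duration 200
  write_fixations(make_fixation(0, 200, cx = 10), p)
  one <- read_fixations(p)
  expect_identical(nrow(one), 1L)
  expect_equal(one$duration, 200)

  # round-trip of a simulated 50-fixation set
  sim <- simulate_gaze(simulation_params(n_fixations = 50, seed = 11,
                                         noise_rms = 0.05))
  det <- detect_fixations(sim$recording, detection_preset("high_precision"))
  write_fixations(det$fixations, p)
  back <- read_fixations(p)
  surv <- det$fixations$surviving[, names(back)]
  expect_identical(nrow(back), nrow(surv))
  expect_identical(back$n_samples, surv$n_samples)
  expect_equal(back$onset, surv$onset, tolerance = 1e-8)
  expect_equal(back$rms, surv$rms, tolerance = 1e-8)
  expect_identical(back$merged, surv$merged)

  # overlapping intervals refuse to serialize
  bad <- rbind(make_fixation(0, 300, 1), make_fixation(200, 400, 1))
  expect_error(write_fixations(bad, p), "overlap")
})

test_that("shipped presets carry the published parameter sets", {
  hi <- detection_preset("high_precision")
  expect_equal(hi$interpolation_latency, 60)
  expect_equal(hi$velocity_threshold, 9)
  expect_equal(hi$max_interpolation_displacement, 0.25)
  expect_equal(hi$degrees_per_pixel, 0.0177)
  expect_equal(hi$merge_max_distance, 0.24)
  expect_equal(hi$merge_max_gap, 50)
  expect_equal(hi$max_rms_per_fixation, 0.24)
  expect_equal(hi$min_fixation_duration, 99)

  lo <- detection_preset("low_precision")
  expect_equal(lo$velocity_threshold, 20)
  expect_equal(lo$merge_max_distance, 0.35)
  expect_equal(lo$max_rms_per_fixation, 0.21)
  expect_equal(lo$min_fixation_duration, 120)
})

test_that("load_params resolves presets, overrides, and validates", {
  p <- withr::local_tempfile(fileext = ".json")
  writeLines('{"preset": "high_precision"}', p)
  expect_equal(load_params(p)$velocity_threshold, 9)

  writeLines('{"preset": "low_precision", "velocity_threshold": 15}', p)
  got <- load_params(p)
  expect_equal(got$velocity_threshold, 15)
  expect_equal(got$min_fixation_duration, 120)

  writeLines('{"preset": "high_precision", "velocity_threshold": -1}', p)
  expect_error(load_params(p), "velocity_threshold")

  writeLines('{"velocity_threshold": 9}', p)
  expect_error(load_params(p), "missing key")

  writeLines('{"preset": "high_precision", "velocty_treshold": 9}', p)
  expect_error(load_params(p), "unknown config key")

  # write_params -> load_params is a fixed point
  write_params(detection_preset("low_precision"), p)
  expect_equal(unclass(load_params(p)),
               unclass(detection_preset("low_precision")))
})

test_that("merge distances above 0.45 deg warn", {
  expect_warning(detection_params(merge_max_distance = 0.5), "0.45")
  expect_silent(detection_params(merge_max_distance = 0.45))
})
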