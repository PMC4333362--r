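test_that("segmentation handles the basic shapes", {
  # constant available trace -> one fixation spanning the recording
  tr <- make_trace(rep(5, 12))
  v <- compute_velocity(tr, 0.0177)
  seg <- segment_by_velocity(tr, v, 9)
  expect_identical(nrow(seg), 1L)
  expect_identical(seg$label, "fixation")
  expect_equal(seg$onset, 0)
  expect_equal(seg$offset, 12 * 1000 / 120)

  # one velocity spike at sample k -> fixation, saccade, fixation
  v2 <- rep(0, 12); v2[6] <- 50
  seg2 <- segment_by_velocity(tr, v2, 9)
  expect_identical(seg2$label, c("fixation", "saccade", "fixation"))
  expect_identical(seg2$i0, c(1L, 6L, 7L))

  # all-missing trace -> empty segmentation with a warning
  tr3 <- make_trace(rep(NA_real_, 10))
  expect_warning(seg3 <- segment_by_velocity(tr3, rep(NA_real_, 10), 9),
                 "no available samples")
  expect_identical(nrow(seg3), 0L)
})

test_that("segmentation matches the brute-force oracle on random traces", {
  for (seed in 1:10) {
    tr <- random_trace(n = 500, seed = seed)
    v <- compute_velocity(tr, 0.0177)
    seg <- segment_by_velocity(tr, v, 40)
    orc <- oracle_segments(tr, v, 40)
    expect_identical(seg$label, orc$label)
    expect_identical(seg$i0, orc$i0)
    expect_identical(seg$i1, orc$i1)
    # tiling invariants: contiguous, label change at every boundary
    if (nrow(seg) > 1L) {
      expect_equal(seg$onset[-1], seg$offset[-nrow(seg)])
      expect_true(all(seg$label[-1] != seg$label[-nrow(seg)]))
    }
  }
})

test_that("raising the velocity threshold never adds saccadic samples", {
  tr <- random_trace(n = 800, seed = 42)
  v <- compute_velocity(tr, 0.0177)
  nsac <- function(thr) {
    seg <- segment_by_velocity(tr, v, thr)
    sac <- seg$label == "saccade"
    sum(seg$i1[sac] - seg$i0[sac] + 1L)
  }
  counts <- vapply(c(5, 10, 20, 40, 80, 160), nsac, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("interpolation gates behave as specified", {
  params <- detection_preset("high_precision")  # latency 60, displacement 0.25
  rate <- 120; dt <- 1000 / rate

  gap_trace <- function(gap_ms, shift_px = 0) {
    n_gap <- round(gap_ms / dt)
    x <- c(rep(100, 20), rep(NA, n_gap), rep(100 + shift_px, 20))
    make_trace(x, rep(200, length(x)), rate)
  }

  # 70 ms gap (> 60 ms latency) -> untouched
  tr <- gap_trace(70)
  out <- interpolate_gaps(tr, compute_velocity(tr, 0.0177), params)
  expect_identical(out$available, tr$available)
  expect_identical(attr(out, "n_gaps_filled"), 0L)

  # 40 ms gap, identical flanking centroids -> filled, no velocity spike
  tr <- gap_trace(40)
  v <- compute_velocity(tr, 0.0177)
  out <- interpolate_gaps(tr, v, params)
  expect_true(all(out$available))
  expect_identical(attr(out, "n_gaps_filled"), 1L)
  expect_true(any(out$interpolated))
  v2 <- compute_velocity(out, 0.0177)
  seg <- segment_by_velocity(out, v2, params$velocity_threshold)
  expect_identical(seg$label, "fixation")   # one clean fixation, no spike

  # flanking centroids 1.0 deg apart (> 0.25) -> displacement gate blocks
  tr <- gap_trace(40, shift_px = 1.0 / 0.0177)
  out <- interpolate_gaps(tr, compute_velocity(tr, 0.0177), params)
  expect_identical(attr(out, "n_gaps_filled"), 0L)
  expect_identical(out$available, tr$available)

  # a gap at the recording edge is never interpolated
  x <- c(rep(NA, 3), rep(100, 30))
  tr <- make_trace(x, rep(0, length(x)), rate)
  out <- interpolate_gaps(tr, compute_velocity(tr, 0.0177), params)
  expect_identical(attr(out, "n_gaps_filled"), 0L)
})

test_that("interpolation never alters available samples nor long gaps", {
  params <- detection_preset("high_precision")
  for (seed in 1:5) {
    tr <- random_trace(n = 600, seed = seed)
    v <- compute_velocity(tr, 0.0177)
    out <- interpolate_gaps(tr, v, params)
    was <- tr$available
    expect_equal(out$x[was], tr$x[was])
    expect_equal(out$y[was], tr$y[was])
    expect_true(all(out$available[was]))
    # every filled sample belongs to a gap no longer than the latency
    filled <- which(out$interpolated & !was)
    if (length(filled)) {
      runs <- split(filled, cumsum(c(1, diff(filled) > 1)))
      for (r in runs) {
        expect_lte(length(r) * 1000 / 120, params$interpolation_latency)
      }
    }
  }
})

test_that("detect_fixations recovers a clean simulated scanpath", {
  params <- detection_preset("high_precision")
  sim <- simulate_gaze(simulation_params(
    n_fixations = 5, seed = 8, noise_rms = 0,
    fixation_duration_range = c(300, 700)
  ))
  det <- detect_fixations(sim$recording, params)
  expect_identical(nrow(det$fixations$surviving), 5L)
  rep <- score_recovery(det, sim$truth)
  expect_equal(rep$hit_rate, 1.0)
  dt <- 1000 / 120
  expect_lte(rep$mean_onset_error, dt)
  expect_lte(rep$mean_offset_error, dt)
})

test_that("an in-fixation gap splits a fixation unless interpolated", {
  base <- simulation_params(
    n_fixations = 6, seed = 21, noise_rms = 0,
    fixation_duration_range = c(300, 700),
    gap_prob = 1e-9, gap_duration_range = c(40, 40)
  )
  gappy <- simulation_params(
    n_fixations = 6, seed = 21, noise_rms = 0,
    fixation_duration_range = c(300, 700),
    gap_prob = 1, gap_duration_range = c(40, 40)
  )
  params <- detection_preset("high_precision")
  n_clean <- nrow(detect_fixations(simulate_gaze(base)$recording,
                                   params)$fixations$surviving)
  sim <- simulate_gaze(gappy)
  n_gaps <- nrow(sim$truth$gaps)
  expect_gt(n_gaps, 0)

  with_interp <- detect_fixations(sim$recording, params)
  expect_identical(nrow(with_interp$fixations$surviving), n_clean)
  expect_identical(with_interp$counts[["gaps_interpolated"]], n_gaps)

  without <- detect_fixations(sim$recording, disable_interpolation(params))
  expect_identical(nrow(without$fixations$surviving),
                   n_clean + n_gaps)  # each gap splits one fixation in two
})

test_that("a fully missing recording yields zero fixations with a warning", {
  rec <- gaze_recording(
    time = seq(0, 99) * 25 / 3,
    left_x = rep(NA_real_, 100), left_y = rep(NA_real_, 100),
    right_x = rep(NA_real_, 100), right_y = rep(NA_real_, 100),
    sampling_rate = 120
  )
  expect_warning(det <- detect_fixations(rec, detection_preset("high_precision")),
                 "no available samples")
  expect_identical(nrow(det$fixations$surviving), 0L)
})

test_that("detection is deterministic", {
  sim <- simulate_gaze(simulation_params(n_fixations = 8, seed = 3,
                                         noise_rms = 0.2, gap_prob = 0.3))
  params <- detection_preset("low_precision")
  a <- detect_fixations(sim$recording, params)
  b <- detect_fixations(sim$recording, params)
  expect_identical(a$fixations$surviving, b$fixations$surviving)
  expect_identical(a$fixations$rejected, b$fixations$rejected)
  expect_identical(a$counts, b$counts)
})

test_that("a high threshold merges fixations split by small saccades", {
  # 2 px saccade amplitude at 120 Hz: a 35 deg/s threshold cannot see the
  # saccades, one long fixation results; a low threshold separates them
  amp_deg <- 2 * 0.0177
  sim <- simulate_gaze(simulation_params(
    n_fixations = 4, seed = 12, noise_rms = 0,
    saccade_amplitude = amp_deg, saccade_duration = 30,
    fixation_duration_range = c(300, 500)
  ))
  tr <- combine_eyes(sim$recording)
  v <- compute_velocity(tr, 0.0177)  # raw: 2 px/sample peaks ~2.1 deg/s
  seg_hi <- segment_by_velocity(tr, v, 35)
  seg_lo <- segment_by_velocity(tr, v, 1)
  expect_identical(sum(seg_hi$label == "fixation"), 1L)
  expect_gt(sum(seg_lo$label == "fixation"), 1L)
})
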