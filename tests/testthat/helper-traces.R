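# fixtures built in code: tiny traces, recordings, and an independent
# run-length-encoding oracle for velocity segmentation

# bare trace from coordinate vectors (pixels); NA = missing sample
make_trace <- function(x, y = rep(0, length(x)), rate = 120,
                       single_eye = rep(FALSE, length(x)),
                       pupil = rep(NA_real_, length(x))) {
  n <- length(x)
  tr <- data.frame(
    time = (seq_len(n) - 1) * 1000 / rate,
    x = x, y = y,
    available = !is.na(x) & !is.na(y),
    single_eye = single_eye, interpolated = FALSE, pupil = pupil
  )
  attr(tr, "sampling_rate") <- rate
  class(tr) <- c("gaze_trace", "data.frame")
  tr
}

# binocular recording with both eyes at the same coordinates
make_rec <- function(x, y = rep(0, length(x)), rate = 120) {
  n <- length(x)
  gaze_recording(
    time = (seq_len(n) - 1) * 1000 / rate,
    left_x = x, left_y = y, right_x = x, right_y = y,
    sampling_rate = rate
  )
}

# hand-built fixation row for post-hoc tests (coordinates in pixels)
make_fixation <- function(onset, offset, cx, cy = 0, rms = 0,
                          n_samples = 10L, pupil = NA_real_) {
  data.frame(
    onset = onset, offset = offset, duration = offset - onset,
    centroid_x = cx, centroid_y = cy, rms = rms,
    n_samples = as.integer(n_samples), n_interpolated = 0L,
    single_eye_fraction = 0, pupil_mean = pupil,
    stringsAsFactors = FALSE
  )
}

# independent oracle: label every sample, then run-length encode with a
# plain loop (no shared code with segment_by_velocity)
oracle_segments <- function(trace, v, threshold) {
  n <- nrow(trace)
  lab <- character(n)
  for (i in seq_len(n)) {
    lab[i] <- if (!trace$available[i]) "gap"
              else if (!is.na(v[i]) && v[i] > threshold) "saccade"
              else "fixation"
  }
  out <- list()
  start <- 1L
  for (i in seq_len(n)) {
    if (i == n || lab[i + 1L] != lab[i]) {
      out[[length(out) + 1L]] <- data.frame(
        label = lab[start], i0 = start, i1 = i, stringsAsFactors = FALSE
      )
      start <- i + 1L
    }
  }
  do.call(rbind, out)
}

# random trace with gaps for property tests
random_trace <- function(n = 1000, rate = 120, seed = 1) {
  set.seed(seed)
  x <- cumsum(stats::rnorm(n, 0, 4))
  y <- cumsum(stats::rnorm(n, 0, 4))
  drop <- stats::runif(n) < 0.08
  x[drop] <- NA; y[drop] <- NA
  make_trace(x, y, rate)
}

disable_interpolation <- function(params) {
  do.call(detection_params,
          modifyList(unclass(params), list(interpolation_latency = 0)))
}
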