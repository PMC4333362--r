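#' Parameters for the synthetic gaze simulator
#'
#' Describes an infant-like recording: alternating fixations and saccades
#' (optionally with smooth-pursuit ramps), binocular positional jitter
#' calibrated so the measured intersample RMS precision of the combined
#' trace equals `noise_rms`, missing-data gaps inside fixations, and
#' single-eye episodes.  A seed is mandatory: the same parameters and seed
#' give a bit-identical recording.
#'
#' @param sampling_rate Hz.
#' @param n_fixations number of fixations (the recording starts and ends
#'   with one).
#' @param fixation_duration_range ms, `c(min, max)`; durations drawn
#'   uniformly.
#' @param saccade_amplitude deg; displacement of each saccade.
#' @param saccade_duration ms; each saccade follows a minimum-jerk
#'   (smooth sigmoidal) position profile, so peak velocity scales as
#'   `1.875 * amplitude / duration`.
#' @param pursuit optional smooth-pursuit ramps: a list
#'   `list(n = , velocity = , duration = )` (deg/s, ms); each ramp is
#'   inserted after a randomly chosen fixation and labelled `"pursuit"`
#'   in the ground truth (not a fixation).
#' @param noise_rms target intersample RMS precision of the combined-eye
#'   trace, deg.  Per-eye, per-axis jitter sigma is `noise_rms / sqrt(2)`,
#'   so the two-eye average has per-axis sigma `noise_rms / 2` and the
#'   expected intersample RMS (difference of two such samples, two axes)
#'   equals `noise_rms`.
#' @param gap_prob probability that a fixation contains one both-eye
#'   missing-data gap (centred in the fixation).
#' @param gap_duration_range ms, `c(min, max)` for injected gaps.
#' @param single_eye_prob probability that a fixation contains an episode
#'   where one eye goes undetected.
#' @param single_eye_duration ms.
#' @param vergence_offset horizontal offset between the two eyes, deg.
#' @param degrees_per_pixel deg/px.
#' @param screen screen bounds in pixels, `c(width, height)`.
#' @param pupil_baseline simulated pupil size, arbitrary units.
#' @param seed integer RNG seed (mandatory).
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(sampling_rate = 120,
                              n_fixations = 10,
                              fixation_duration_range = c(200, 800),
                              saccade_amplitude = 5,
                              saccade_duration = 30,
                              pursuit = NULL,
                              noise_rms = 0,
                              gap_prob = 0,
                              gap_duration_range = c(40, 40),
                              single_eye_prob = 0,
                              single_eye_duration = 100,
                              vergence_offset = 0,
                              degrees_per_pixel = 0.0177,
                              screen = c(1920, 1080),
                              pupil_baseline = 600,
                              seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L) {
    stop("gazefix_error_params: a single integer seed is mandatory",
         call. = FALSE)
  }
  if (n_fixations < 1L || sampling_rate <= 0 ||
      any(fixation_duration_range <= 0) || saccade_amplitude <= 0 ||
      saccade_duration <= 0 || noise_rms < 0 ||
      gap_prob < 0 || gap_prob > 1 || single_eye_prob < 0 ||
      single_eye_prob > 1 || degrees_per_pixel <= 0) {
    stop("gazefix_error_params: invalid simulation parameters",
         call. = FALSE)
  }
  if (saccade_duration >= min(fixation_duration_range)) {
    stop("gazefix_error_params: saccade_duration must be shorter than ",
         "the shortest fixation", call. = FALSE)
  }
  structure(as.list(environment()), class = "simulation_params")
}

# minimum-jerk position profile on [0, 1]
minjerk <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

#' Simulate a gaze recording with ground-truth events
#'
#' Builds a piecewise trajectory — constant position during fixations,
#' minimum-jerk sigmoidal displacement during saccades, constant-velocity
#' ramps during pursuit — then renders two eyes with independent Gaussian
#' jitter, injects missing-data gaps and single-eye episodes, and returns
#' both the raw recording and the true event segmentation.
#'
#' The ground truth records the underlying oculomotor state: a fixation
#' interrupted by an injected data-loss gap is still one true fixation
#' (recovering it is exactly what the interpolation stage is for);
#' injected gaps are listed separately in `truth$gaps`.
#'
#' @param params a [simulation_params()] record.
#' @return A list of class `gaze_simulation` with elements `recording`
#'   (a [gaze_recording()]) and `truth` (list: `events` data.frame with
#'   `label`, `onset`, `offset`, `centroid_x_deg`, `centroid_y_deg`;
#'   `sample_labels` character vector aligned with the samples; `gaps`
#'   data.frame of injected gaps).
#' @export
simulate_gaze <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  p <- params
  set.seed(as.integer(p$seed))
  dpp <- p$degrees_per_pixel
  dt <- 1000 / p$sampling_rate

  fix_dur <- stats::runif(p$n_fixations, p$fixation_duration_range[1],
                          p$fixation_duration_range[2])

  # which fixations are followed by a pursuit ramp
  pursuit_after <- integer()
  if (!is.null(p$pursuit)) {
    n_pur <- min(p$pursuit$n, p$n_fixations - 1L)
    pursuit_after <- sort(sample.int(p$n_fixations - 1L, n_pur))
  }

  # fixation positions: random-direction saccades of fixed amplitude,
  # kept inside a 10% screen margin
  amp_px <- p$saccade_amplitude / dpp
  margin <- 0.1 * p$screen
  lo <- margin; hi <- p$screen - margin
  clamp_ok <- function(pos) all(pos >= lo & pos <= hi)

  events <- list()
  pos <- p$screen / 2
  t <- 0
  add_event <- function(label, dur, p0, p1) {
    events[[length(events) + 1L]] <<- data.frame(
      label = label, onset = t, offset = t + dur,
      x0 = p0[1], y0 = p0[2], x1 = p1[1], y1 = p1[2],
      stringsAsFactors = FALSE
    )
    t <<- t + dur
  }
  step_to <- function(pos, dist) {
    for (try in 1:200) {
      ang <- stats::runif(1, 0, 2 * pi)
      cand <- pos + dist * c(cos(ang), sin(ang))
      if (clamp_ok(cand)) return(cand)
    }
    p$screen / 2  # degenerate screens: fall back to centre
  }

  for (i in seq_len(p$n_fixations)) {
    add_event("fixation", fix_dur[i], pos, pos)
    if (i %in% pursuit_after) {
      ramp_px <- (p$pursuit$velocity / dpp) * (p$pursuit$duration / 1000)
      target <- step_to(pos, ramp_px)
      add_event("pursuit", p$pursuit$duration, pos, target)
      pos <- target
    }
    if (i < p$n_fixations) {
      target <- step_to(pos, amp_px)
      add_event("saccade", p$saccade_duration, pos, target)
      pos <- target
    }
  }
  events <- do.call(rbind, events)
  total <- t

  time <- seq(0, total - dt / 2, by = dt)
  n <- length(time)
  ev <- findInterval(time, events$onset)
  tau <- (time - events$onset[ev]) /
    (events$offset[ev] - events$onset[ev])
  frac <- ifelse(events$label[ev] == "saccade", minjerk(tau),
                 ifelse(events$label[ev] == "pursuit", tau, 0))
  x <- events$x0[ev] + frac * (events$x1[ev] - events$x0[ev])
  y <- events$y0[ev] + frac * (events$y1[ev] - events$y0[ev])
  sample_labels <- events$label[ev]

  # per-eye jitter: sigma = noise_rms / sqrt(2) per axis (see
  # simulation_params); vergence shifts the eyes horizontally apart
  sig_px <- (p$noise_rms / sqrt(2)) / dpp
  verg_px <- (p$vergence_offset / dpp) / 2
  jit <- function() if (sig_px > 0) stats::rnorm(n, 0, sig_px) else numeric(n)
  left_x <- x - verg_px + jit(); left_y <- y + jit()
  right_x <- x + verg_px + jit(); right_y <- y + jit()
  pupil_left <- p$pupil_baseline + stats::rnorm(n, 0, 5)
  pupil_right <- p$pupil_baseline + stats::rnorm(n, 0, 5)

  left_valid <- rep(TRUE, n); right_valid <- rep(TRUE, n)

  fx_rows <- which(events$label == "fixation")
  gaps <- list()
  for (k in fx_rows) {
    if (stats::runif(1) < p$gap_prob) {
      g <- stats::runif(1, p$gap_duration_range[1], p$gap_duration_range[2])
      dur <- events$offset[k] - events$onset[k]
      if (g >= dur - 4 * dt) next  # gap must leave fixation samples around it
      mid <- (events$onset[k] + events$offset[k]) / 2
      idx <- which(time >= mid - g / 2 & time < mid + g / 2)
      if (!length(idx)) next
      left_valid[idx] <- FALSE
      right_valid[idx] <- FALSE
      gaps[[length(gaps) + 1L]] <- data.frame(
        fixation = k, onset = time[idx[1]],
        offset = time[idx[length(idx)]] + dt
      )
    }
  }
  for (k in fx_rows) {
    if (stats::runif(1) < p$single_eye_prob) {
      dur <- events$offset[k] - events$onset[k]
      d <- min(p$single_eye_duration, dur / 2)
      start <- stats::runif(1, events$onset[k], events$offset[k] - d)
      idx <- which(time >= start & time < start + d)
      eye <- if (stats::runif(1) < 0.5) "left" else "right"
      if (eye == "left") left_valid[idx] <- FALSE
      else right_valid[idx] <- FALSE
    }
  }

  rec <- gaze_recording(
    time = time, left_x = left_x, left_y = left_y,
    right_x = right_x, right_y = right_y,
    left_valid = left_valid, right_valid = right_valid,
    pupil_left = pupil_left, pupil_right = pupil_right,
    sampling_rate = p$sampling_rate
  )

  truth_events <- data.frame(
    label = events$label, onset = events$onset, offset = events$offset,
    centroid_x_deg = ifelse(events$label == "fixation",
                            events$x0 * dpp, NA_real_),
    centroid_y_deg = ifelse(events$label == "fixation",
                            events$y0 * dpp, NA_real_),
    stringsAsFactors = FALSE
  )
  gaps <- if (length(gaps)) do.call(rbind, gaps) else
    data.frame(fixation = integer(), onset = numeric(), offset = numeric())

  structure(
    list(recording = rec,
         truth = list(events = truth_events, sample_labels = sample_labels,
                      gaps = gaps),
         params = params),
    class = "gaze_simulation"
  )
}

#' Score recovery of detected fixations against ground truth
#'
#' Greedy one-to-one matching of detected to true fixations by maximal
#' temporal overlap.  A matched pair counts as a hit when its overlap is
#' positive and (if `tolerance` is finite) both |onset error| and
#' |offset error| are within `tolerance` ms.
#'
#' @param detected a `fixation_set` (its surviving fixations are used), a
#'   `fixation_detection`, or a fixation data.frame.
#' @param truth the `truth` element of a [simulate_gaze()] result (or its
#'   `events` data.frame).
#' @param tolerance ms; default `Inf` (any positive overlap is a hit).
#' @return A list of class `recovery_report`: `n_true`, `n_detected`,
#'   `n_hits`, `hit_rate`, `false_detection_rate`, `mean_onset_error`,
#'   `mean_offset_error`, `max_onset_error`, `max_offset_error` (ms),
#'   `mean_duration_ratio` (detected / true).
#' @export
score_recovery <- function(detected, truth, tolerance = Inf) {
  if (inherits(detected, "fixation_detection")) {
    detected <- detected$fixations
  }
  det <- if (inherits(detected, "fixation_set")) detected$surviving
         else detected
  ev <- if (is.data.frame(truth)) truth else truth$events
  tru <- ev[ev$label == "fixation", , drop = FALSE]

  n_det <- nrow(det); n_true <- nrow(tru)
  if (n_det == 0L || n_true == 0L) {
    return(structure(list(
      n_true = n_true, n_detected = n_det, n_hits = 0L,
      hit_rate = 0, false_detection_rate = if (n_det) 1 else 0,
      mean_onset_error = NA_real_, mean_offset_error = NA_real_,
      max_onset_error = NA_real_, max_offset_error = NA_real_,
      mean_duration_ratio = NA_real_
    ), class = "recovery_report"))
  }

  ov <- matrix(0, n_det, n_true)
  for (i in seq_len(n_det)) {
    ov[i, ] <- pmax(0, pmin(det$offset[i], tru$offset) -
                       pmax(det$onset[i], tru$onset))
  }
  onset_err <- offset_err <- dur_ratio <- numeric()
  n_hits <- 0L
  repeat {
    m <- which(ov == max(ov), arr.ind = TRUE)[1, , drop = TRUE]
    if (ov[m[1], m[2]] <= 0) break
    oe <- abs(det$onset[m[1]] - tru$onset[m[2]])
    fe <- abs(det$offset[m[1]] - tru$offset[m[2]])
    if (oe <= tolerance && fe <= tolerance) {
      n_hits <- n_hits + 1L
      onset_err <- c(onset_err, oe)
      offset_err <- c(offset_err, fe)
      dur_ratio <- c(dur_ratio,
                     (det$offset[m[1]] - det$onset[m[1]]) /
                     (tru$offset[m[2]] - tru$onset[m[2]]))
    }
    ov[m[1], ] <- -1
    ov[, m[2]] <- -1
  }

  structure(list(
    n_true = n_true, n_detected = n_det, n_hits = n_hits,
    hit_rate = n_hits / n_true,
    false_detection_rate = (n_det - n_hits) / n_det,
    mean_onset_error = if (n_hits) mean(onset_err) else NA_real_,
    mean_offset_error = if (n_hits) mean(offset_err) else NA_real_,
    max_onset_error = if (n_hits) max(onset_err) else NA_real_,
    max_offset_error = if (n_hits) max(offset_err) else NA_real_,
    mean_duration_ratio = if (n_hits) mean(dur_ratio) else NA_real_
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(
    "<recovery_report> hit rate %.3f (%d/%d), false detections %.3f (%d extra)\n",
    x$hit_rate, x$n_hits, x$n_true, x$false_detection_rate,
    x$n_detected - x$n_hits
  ))
  if (!is.na(x$mean_onset_error)) {
    cat(sprintf(
      "  mean |onset error| %.1f ms, |offset error| %.1f ms, duration ratio %.3f\n",
      x$mean_onset_error, x$mean_offset_error, x$mean_duration_ratio
    ))
  }
  invisible(x)
}
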