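#' Build the per-fixation statistics table from a segmentation
#'
#' One row per fixation segment: onset/offset/duration, centroid over the
#' segment's samples (pixels and degrees), intersample RMS in degrees,
#' sample counts, single-eye and interpolation bookkeeping, and the pupil
#' mean over the segment.  The column `gap_before` records whether any
#' missing-data sample separates a fixation from its predecessor; the
#' post-hoc merge step only bridges separators free of missing data.
#'
#' @param seg an `event_segmentation`.
#' @param trace the `gaze_trace` the segmentation was computed on.
#' @param dpp degrees per pixel.
#' @return A fixation data.frame.
#' @export
fixations_from_segmentation <- function(seg, trace, dpp) {
  fx <- which(seg$label == "fixation")
  if (!length(fx)) {
    df <- as_fixation_df(NULL)
    df$gap_before <- logical()
    return(df)
  }
  rows <- lapply(fx, function(k) {
    idx <- seg$i0[k]:seg$i1[k]
    x <- trace$x[idx]; y <- trace$y[idx]
    pup <- trace$pupil[idx]
    data.frame(
      onset = seg$onset[k], offset = seg$offset[k],
      duration = seg$offset[k] - seg$onset[k],
      centroid_x = mean(x), centroid_y = mean(y),
      rms = intersample_rms(x, y, dpp),
      n_samples = length(idx),
      n_interpolated = sum(trace$interpolated[idx]),
      single_eye_fraction = mean(trace$single_eye[idx]),
      pupil_mean = if (all(is.na(pup))) NA_real_ else mean(pup, na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  df$centroid_x_deg <- df$centroid_x * dpp
  df$centroid_y_deg <- df$centroid_y * dpp
  df <- as_fixation_df(df)
  # does any missing-data sample separate this fixation from the previous?
  gap_before <- rep(NA, length(fx))
  for (j in seq_along(fx)) {
    k <- fx[j]
    gap_before[j] <- if (j == 1L) FALSE else {
      prev <- fx[j - 1L]
      between <- setdiff(seq(seg$i0[prev], seg$i1[k]),
                         c(seg$i0[prev]:seg$i1[prev], seg$i0[k]:seg$i1[k]))
      length(between) > 0L && any(!trace$available[between])
    }
  }
  df$gap_before <- gap_before
  df
}

#' Detect fixations in a raw gaze recording
#'
#' The full pipeline: (1) average the two eyes ([combine_eyes()]) and
#' smooth with the bilateral filter ([bilateral_smooth()]); (2)
#' interpolate short in-fixation missing-data gaps ([interpolate_gaps()])
#' and recompute velocity; (3) segment by velocity threshold
#' ([segment_by_velocity()]); (4) apply the three ordered post-hoc
#' validation filters ([posthoc_validate()]).
#'
#' @param rec a [gaze_recording()].
#' @param params a [detection_params()] record (see [detection_preset()]
#'   for the shipped high/low-precision presets).
#' @param verbose emit per-stage counts as messages?
#' @return An object of class `fixation_detection`: a list with
#'   `fixations` (a `fixation_set`, see [posthoc_validate()]),
#'   `segmentation` (post-interpolation `event_segmentation`), `trace`
#'   (the smoothed, interpolated `gaze_trace`), and `counts` (named vector:
#'   gaps interpolated, fixations merged/rejected per criterion).
#' @export
#' @examples
#' sim <- simulate_gaze(simulation_params(n_fixations = 5, seed = 1))
#' det <- detect_fixations(sim$recording, detection_preset("high_precision"))
#' nrow(det$fixations$surviving)
detect_fixations <- function(rec, params = detection_preset("high_precision"),
                             verbose = FALSE) {
  stopifnot(inherits(rec, "gaze_recording"),
            inherits(params, "detection_params"))
  dpp <- params$degrees_per_pixel

  trace <- combine_eyes(rec, include_single_eye = params$include_single_eye)
  trace <- bilateral_smooth(trace, params$smoothing, dpp)
  v <- compute_velocity(trace, dpp)
  trace <- interpolate_gaps(trace, v, params)
  n_gaps_filled <- attr(trace, "n_gaps_filled")
  v <- compute_velocity(trace, dpp)
  seg <- segment_by_velocity(trace, v, params$velocity_threshold)

  pre <- fixations_from_segmentation(seg, trace, dpp)
  fixset <- posthoc_validate(pre, params)

  counts <- c(gaps_interpolated = n_gaps_filled, fixset$counts)
  if (verbose) {
    message(sprintf(
      "detect_fixations: interpolated %d gap(s); merged: %d, rms-rejected: %d, duration-rejected: %d",
      n_gaps_filled, fixset$counts[["merged"]],
      fixset$counts[["rms_rejected"]], fixset$counts[["duration_rejected"]]
    ))
  }
  structure(
    list(fixations = fixset, segmentation = seg, trace = trace,
         counts = counts),
    class = "fixation_detection"
  )
}

#' @export
print.fixation_detection <- function(x, ...) {
  cat(sprintf(
    "<fixation_detection> %d surviving fixation(s), %d rejected\n",
    nrow(x$fixations$surviving), nrow(x$fixations$rejected)
  ))
  cat(sprintf(
    "  gaps interpolated: %d | merged: %d | rms-rejected: %d | duration-rejected: %d\n",
    x$counts[["gaps_interpolated"]], x$counts[["merged"]],
    x$counts[["rms_rejected"]], x$counts[["duration_rejected"]]
  ))
  invisible(x)
}
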