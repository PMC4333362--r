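#' Recording-level RMS spatial precision
#'
#' Root mean square of the Euclidean distances between consecutive
#' available samples, in degrees — the manufacturer-convention precision
#' measure.  In `"within_fixation"` mode only pairs lying inside detected
#' fixation segments contribute (precision during stable gaze, the usual
#' convention); `"all"` mode uses every consecutive available pair and
#' therefore also absorbs saccadic displacements.
#'
#' Precision is offset-invariant: shifting the whole trace by a constant
#' leaves it unchanged (spatial accuracy and precision are distinct
#' quantities).
#'
#' @param trace a `gaze_trace` (raw combined or smoothed).
#' @param dpp degrees per pixel.
#' @param mode `"all"` or `"within_fixation"`.
#' @param segmentation an `event_segmentation`, required for
#'   `"within_fixation"` mode.
#' @return RMS precision in degrees.
#' @export
rms_precision <- function(trace, dpp, mode = c("all", "within_fixation"),
                          segmentation = NULL) {
  mode <- match.arg(mode)
  if (sum(trace$available) < 2L) {
    stop("gazefix_error_undefined: fewer than 2 available samples",
         call. = FALSE)
  }
  if (mode == "all") {
    return(intersample_rms(ifelse(trace$available, trace$x, NA_real_),
                           ifelse(trace$available, trace$y, NA_real_), dpp))
  }
  if (is.null(segmentation)) {
    stop("gazefix_error_params: within_fixation mode needs a segmentation",
         call. = FALSE)
  }
  fx <- which(segmentation$label == "fixation")
  d2 <- unlist(lapply(fx, function(k) {
    idx <- segmentation$i0[k]:segmentation$i1[k]
    x <- trace$x[idx]; y <- trace$y[idx]
    ok <- trace$available[idx] & !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 2L) return(numeric())
    (diff(x)^2 + diff(y)^2) * dpp^2
  }))
  if (!length(d2)) {
    stop("gazefix_error_undefined: no within-fixation sample pairs",
         call. = FALSE)
  }
  sqrt(mean(d2))
}

#' Data loss of a recording
#'
#' The fraction of samples with no valid gaze estimate — a standard
#' quality metric, typically driven by unreliable pupil or corneal
#' reflection detection.
#'
#' @param rec a [gaze_recording()].
#' @return A named list: `binocular` (neither eye valid), `left`, `right`
#'   (per-eye loss fractions).
#' @export
data_loss <- function(rec) {
  stopifnot(inherits(rec, "gaze_recording"))
  s <- rec$samples
  list(
    binocular = mean(!s$left_valid & !s$right_valid),
    left = mean(!s$left_valid),
    right = mean(!s$right_valid)
  )
}

#' Per-axis dispersion (standard deviation) of a trace
#'
#' The dispersion-from-the-mean view of precision: sample standard
#' deviation of the available x and y coordinates, in degrees.
#'
#' @param trace a `gaze_trace`.
#' @param dpp degrees per pixel.
#' @return Named numeric vector `c(x = , y = )` in degrees.
#' @export
sd_dispersion <- function(trace, dpp) {
  ok <- trace$available & !is.na(trace$x) & !is.na(trace$y)
  if (sum(ok) < 2L) {
    stop("gazefix_error_undefined: fewer than 2 available samples",
         call. = FALSE)
  }
  c(x = stats::sd(trace$x[ok]) * dpp, y = stats::sd(trace$y[ok]) * dpp)
}

#' Recording-level quality report
#'
#' Computes the data-quality measures used to stratify participants: RMS
#' spatial precision, per-axis dispersion SD, data loss, and the fraction
#' of single-eye samples.  If `params` is supplied, fixations are detected
#' first and the RMS is computed within fixations (the manufacturer
#' convention); otherwise the RMS is over all available samples of the raw
#' combined-eye trace.
#'
#' @param rec a [gaze_recording()].
#' @param params optional [detection_params()]; enables within-fixation
#'   RMS.
#' @param include_single_eye combine policy when `params` is not given.
#' @return An object of class `quality_report`: list with `rms_precision`
#'   (deg), `rms_mode`, `sd_dispersion_x`, `sd_dispersion_y` (deg),
#'   `data_loss_fraction`, `data_loss_left`, `data_loss_right`,
#'   `single_eye_fraction`, `n_samples`.
#' @export
quality_report <- function(rec, params = NULL, include_single_eye = TRUE) {
  stopifnot(inherits(rec, "gaze_recording"))
  if (!is.null(params)) {
    dpp <- params$degrees_per_pixel
    raw <- combine_eyes(rec, params$include_single_eye)
    det <- detect_fixations(rec, params)
    rms <- rms_precision(raw, dpp, mode = "within_fixation",
                         segmentation = det$segmentation)
    rms_mode <- "within_fixation"
    trace <- raw
  } else {
    dpp <- 0.0177
    trace <- combine_eyes(rec, include_single_eye)
    rms <- rms_precision(trace, dpp, mode = "all")
    rms_mode <- "all"
  }
  loss <- data_loss(rec)
  disp <- sd_dispersion(trace, dpp)
  structure(list(
    rms_precision = rms,
    rms_mode = rms_mode,
    sd_dispersion_x = unname(disp["x"]),
    sd_dispersion_y = unname(disp["y"]),
    data_loss_fraction = loss$binocular,
    data_loss_left = loss$left,
    data_loss_right = loss$right,
    single_eye_fraction = mean(trace$single_eye),
    n_samples = nrow(trace)
  ), class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat("<quality_report>\n")
  cat(sprintf("  RMS precision (%s): %.4f deg\n", x$rms_mode,
              x$rms_precision))
  cat(sprintf("  dispersion SD: x %.4f deg, y %.4f deg\n",
              x$sd_dispersion_x, x$sd_dispersion_y))
  cat(sprintf("  data loss: %.1f%% (left %.1f%%, right %.1f%%)\n",
              100 * x$data_loss_fraction, 100 * x$data_loss_left,
              100 * x$data_loss_right))
  cat(sprintf("  single-eye samples: %.1f%%\n",
              100 * x$single_eye_fraction))
  invisible(x)
}
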