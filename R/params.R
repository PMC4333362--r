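#' Detection parameters
#'
#' Bundles every threshold of the detection pipeline in one validated
#' record.  All spatial thresholds are in degrees of visual angle, the
#' velocity threshold in deg/s, and temporal thresholds in ms; pixel
#' coordinates are converted through the single isotropic
#' `degrees_per_pixel` factor.
#'
#' Two presets are shipped (see [detection_preset()]): `"high_precision"`
#' and `"low_precision"`, the published parameter sets for high- and
#' low-spatial-precision infant recordings.
#'
#' @param interpolation_latency longest missing-data gap (ms) that may be
#'   filled when it lies within a fixation.  `0` disables interpolation.
#' @param velocity_threshold speed (deg/s) above which a sample is flagged
#'   saccadic.
#' @param max_interpolation_displacement maximum distance (deg) between the
#'   centroids of the fixations flanking a gap for the gap to be filled.
#' @param degrees_per_pixel isotropic pixel-to-degree conversion (deg/px).
#' @param merge_max_distance maximum centroid distance (deg) for merging
#'   adjacent fixations.  Values above 0.45 trigger a warning: merging that
#'   far risks bridging genuine short saccades.
#' @param merge_max_gap maximum time (ms) between adjacent fixations for
#'   merging (strict `<`).
#' @param max_rms_per_fixation fixations with intersample RMS (deg) above
#'   this are rejected (strict `>`).
#' @param min_fixation_duration fixations shorter than this (ms) are
#'   rejected (strict `<`).
#' @param include_single_eye keep samples where only one eye was detected?
#'   Recommended `TRUE` for infant data.
#' @param smoothing a [smoothing_params()] record for the bilateral filter.
#'
#' @return An object of class `detection_params`.
#' @seealso [load_params()], [detection_preset()]
#' @export
detection_params <- function(interpolation_latency = 60,
                             velocity_threshold = 9,
                             max_interpolation_displacement = 0.25,
                             degrees_per_pixel = 0.0177,
                             merge_max_distance = 0.24,
                             merge_max_gap = 50,
                             max_rms_per_fixation = 0.24,
                             min_fixation_duration = 99,
                             include_single_eye = TRUE,
                             smoothing = smoothing_params()) {
  num1 <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v)) {
      stop(sprintf("gazefix_error_params: '%s' must be a single number", nm),
           call. = FALSE)
    }
    as.numeric(v)
  }
  p <- list(
    interpolation_latency = num1(interpolation_latency, "interpolation_latency"),
    velocity_threshold = num1(velocity_threshold, "velocity_threshold"),
    max_interpolation_displacement =
      num1(max_interpolation_displacement, "max_interpolation_displacement"),
    degrees_per_pixel = num1(degrees_per_pixel, "degrees_per_pixel"),
    merge_max_distance = num1(merge_max_distance, "merge_max_distance"),
    merge_max_gap = num1(merge_max_gap, "merge_max_gap"),
    max_rms_per_fixation = num1(max_rms_per_fixation, "max_rms_per_fixation"),
    min_fixation_duration = num1(min_fixation_duration, "min_fixation_duration"),
    include_single_eye = isTRUE(include_single_eye),
    smoothing = smoothing
  )
  # interpolation_latency may be 0 (interpolation off); all else > 0
  strict <- c("velocity_threshold", "max_interpolation_displacement",
              "degrees_per_pixel", "merge_max_distance", "merge_max_gap",
              "max_rms_per_fixation", "min_fixation_duration")
  bad <- strict[vapply(p[strict], function(v) v <= 0, logical(1))]
  if (p$interpolation_latency < 0) bad <- c("interpolation_latency", bad)
  if (length(bad)) {
    stop("gazefix_error_params: non-positive threshold(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (p$merge_max_distance > 0.45) {
    warning("merge_max_distance > 0.45 deg is not recommended: ",
            "merging may bridge genuine short saccades", call. = FALSE)
  }
  if (!inherits(smoothing, "smoothing_params")) {
    p$smoothing <- do.call(smoothing_params, as.list(smoothing))
  }
  structure(p, class = "detection_params")
}

#' Bilateral-filter smoothing parameters
#'
#' The bilateral filter replaces each available sample by a weighted mean
#' of its available neighbours, weights being the product of a temporal
#' Gaussian and a positional ("range") Gaussian.  The range kernel is what
#' preserves saccades: neighbours further than a few `range_sigma` in
#' position contribute negligibly, so averaging never crosses a
#' saccade-sized displacement.
#'
#' @param window half-width (ms) of the neighbourhood considered.  Kept
#'   shorter than the minimum fixation duration so the filter never bridges
#'   whole events.
#' @param temporal_sigma sigma (ms) of the temporal Gaussian.
#' @param range_sigma sigma (deg) of the positional Gaussian.
#' @return An object of class `smoothing_params`.
#' @export
smoothing_params <- function(window = 100, temporal_sigma = 20,
                             range_sigma = 0.5) {
  if (any(c(window, temporal_sigma, range_sigma) <= 0)) {
    stop("gazefix_error_params: smoothing parameters must be positive",
         call. = FALSE)
  }
  structure(list(window = window, temporal_sigma = temporal_sigma,
                 range_sigma = range_sigma),
            class = "smoothing_params")
}

#' Shipped parameter presets
#'
#' The two published parameter sets for intercoder-reliability work on
#' infant recordings: one tuned for high-spatial-precision data (velocity
#' threshold 9 deg/s, min fixation 99 ms) and one for low-precision data
#' (20 deg/s, 120 ms, wider merge distance, tighter RMS bound).
#'
#' @param name `"high_precision"` or `"low_precision"`.
#' @return A [detection_params()] object.
#' @export
#' @examples
#' detection_preset("high_precision")$velocity_threshold  # 9
detection_preset <- function(name = c("high_precision", "low_precision")) {
  name <- match.arg(name)
  switch(name,
    high_precision = detection_params(
      interpolation_latency = 60, velocity_threshold = 9,
      max_interpolation_displacement = 0.25, degrees_per_pixel = 0.0177,
      merge_max_distance = 0.24, merge_max_gap = 50,
      max_rms_per_fixation = 0.24, min_fixation_duration = 99
    ),
    low_precision = detection_params(
      interpolation_latency = 60, velocity_threshold = 20,
      max_interpolation_displacement = 0.25, degrees_per_pixel = 0.0177,
      merge_max_distance = 0.35, merge_max_gap = 50,
      max_rms_per_fixation = 0.21, min_fixation_duration = 120
    )
  )
}

#' Load detection parameters from a JSON config
#'
#' The config either selects a preset (`{"preset": "high_precision"}`,
#' optionally overriding individual keys) or declares all eight thresholds
#' explicitly, keys named exactly as the [detection_params()] arguments.
#' A `"smoothing"` section maps onto [smoothing_params()].
#'
#' @param path path to a JSON file.
#' @return A [detection_params()] object.
#' @export
load_params <- function(path) {
  if (!file.exists(path)) {
    stop("gazefix_error_missing_file: no such config: ", path, call. = FALSE)
  }
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  params_from_list(cfg)
}

params_from_list <- function(cfg) {
  base <- if (!is.null(cfg$preset)) {
    unclass(detection_preset(cfg$preset))
  } else {
    required <- c("interpolation_latency", "velocity_threshold",
                  "max_interpolation_displacement", "degrees_per_pixel",
                  "merge_max_distance", "merge_max_gap",
                  "max_rms_per_fixation", "min_fixation_duration")
    missing <- setdiff(required, names(cfg))
    if (length(missing)) {
      stop("gazefix_error_params: config missing key(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    unclass(detection_params())
  }
  cfg$preset <- NULL
  smooth_cfg <- cfg$smoothing
  cfg$smoothing <- NULL
  known <- names(formals(detection_params))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("gazefix_error_params: unknown config key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  base[names(cfg)] <- cfg
  if (!is.null(smooth_cfg)) {
    base$smoothing <- do.call(smoothing_params, as.list(smooth_cfg))
  }
  do.call(detection_params, base)
}

#' Write detection parameters to a JSON config
#'
#' @param params a [detection_params()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "detection_params"))
  out <- unclass(params)
  out$smoothing <- unclass(out$smoothing)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.detection_params <- function(x, ...) {
  cat("<detection_params>\n")
  cat(sprintf("  interpolation latency: %g ms%s\n", x$interpolation_latency,
              if (x$interpolation_latency == 0) " (interpolation off)" else ""))
  cat(sprintf("  velocity threshold: %g deg/s\n", x$velocity_threshold))
  cat(sprintf("  max interpolation displacement: %g deg\n",
              x$max_interpolation_displacement))
  cat(sprintf("  degrees per pixel: %g\n", x$degrees_per_pixel))
  cat(sprintf("  merge: gap < %g ms, distance <= %g deg\n",
              x$merge_max_gap, x$merge_max_distance))
  cat(sprintf("  max RMS per fixation: %g deg\n", x$max_rms_per_fixation))
  cat(sprintf("  min fixation duration: %g ms\n", x$min_fixation_duration))
  cat(sprintf("  include single-eye samples: %s\n", x$include_single_eye))
  invisible(x)
}
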