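#' Construct a raw gaze recording
#'
#' A `gaze_recording` holds one row per eye-tracker sample: a timestamp,
#' per-eye screen coordinates, per-eye validity flags, and (optionally)
#' per-eye pupil size.  Coordinates of samples whose validity flag is
#' `FALSE` are treated as missing regardless of the stored value; that rule
#' is enforced at construction time so downstream code can rely on `NA`
#' alone.
#'
#' @param time numeric vector of timestamps in ms, strictly increasing,
#'   nominally uniform at `1000 / sampling_rate`.
#' @param left_x,left_y,right_x,right_y numeric screen coordinates in
#'   pixels; `NA` where the eye was not detected.  An entirely absent eye
#'   (monocular recording) may be passed as `NULL`.
#' @param left_valid,right_valid logical validity flags per sample.
#'   Defaults to "coordinates present".
#' @param pupil_left,pupil_right optional numeric pupil size per sample,
#'   arbitrary units.
#' @param sampling_rate sampling rate in Hz (positive).
#'
#' @return An object of class `gaze_recording`: a list with elements
#'   `samples` (data.frame) and `sampling_rate`.
#' @export
#' @examples
#' rec <- gaze_recording(
#'   time = c(0, 10, 20), left_x = c(1, 2, 3), left_y = c(1, 1, 1),
#'   right_x = c(1, 2, 3), right_y = c(1, 1, 1), sampling_rate = 100
#' )
#' rec
gaze_recording <- function(time, left_x = NULL, left_y = NULL,
                           right_x = NULL, right_y = NULL,
                           left_valid = NULL, right_valid = NULL,
                           pupil_left = NULL, pupil_right = NULL,
                           sampling_rate) {
  n <- length(time)
  if (n < 2L) {
    stop("gazefix_error_empty: a gaze recording needs at least 2 samples",
         call. = FALSE)
  }
  if (anyNA(time) || any(diff(time) <= 0)) {
    stop("gazefix_error_timestamps: timestamps must be strictly increasing",
         call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      is.na(sampling_rate) || sampling_rate <= 0) {
    stop("gazefix_error_params: sampling_rate must be a positive number",
         call. = FALSE)
  }

  fill <- function(v) if (is.null(v)) rep(NA_real_, n) else as.numeric(v)
  left_x <- fill(left_x); left_y <- fill(left_y)
  right_x <- fill(right_x); right_y <- fill(right_y)
  pupil_left <- fill(pupil_left); pupil_right <- fill(pupil_right)

  stopifnot(length(left_x) == n, length(left_y) == n,
            length(right_x) == n, length(right_y) == n)

  if (is.null(left_valid)) left_valid <- !is.na(left_x) & !is.na(left_y)
  if (is.null(right_valid)) right_valid <- !is.na(right_x) & !is.na(right_y)
  left_valid <- as.logical(left_valid) & !is.na(left_x) & !is.na(left_y)
  right_valid <- as.logical(right_valid) & !is.na(right_x) & !is.na(right_y)
  left_valid[is.na(left_valid)] <- FALSE
  right_valid[is.na(right_valid)] <- FALSE

  # validity is authoritative: invalid samples lose their coordinates
  left_x[!left_valid] <- NA_real_; left_y[!left_valid] <- NA_real_
  right_x[!right_valid] <- NA_real_; right_y[!right_valid] <- NA_real_
  pupil_left[!left_valid] <- NA_real_
  pupil_right[!right_valid] <- NA_real_

  samples <- data.frame(
    time = as.numeric(time),
    left_x = left_x, left_y = left_y,
    right_x = right_x, right_y = right_y,
    left_valid = left_valid, right_valid = right_valid,
    pupil_left = pupil_left, pupil_right = pupil_right
  )
  structure(list(samples = samples, sampling_rate = sampling_rate),
            class = "gaze_recording")
}

#' @export
print.gaze_recording <- function(x, ...) {
  s <- x$samples
  cat(sprintf(
    "<gaze_recording> %d samples @ %g Hz (%.1f s)\n",
    nrow(s), x$sampling_rate, diff(range(s$time)) / 1000
  ))
  cat(sprintf("  left eye valid:  %.1f%%\n", 100 * mean(s$left_valid)))
  cat(sprintf("  right eye valid: %.1f%%\n", 100 * mean(s$right_valid)))
  invisible(x)
}

n_samples <- function(rec) nrow(rec$samples)
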