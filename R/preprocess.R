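#' Combine the two eyes into a single trace
#'
#' Where both eyes are valid the combined position is their arithmetic
#' mean; where exactly one eye is valid the policy is configurable: keep
#' that eye's coordinates (flagged `single_eye`, recommended for infant
#' data, where a hand over one eye is common) or treat the sample as
#' missing (the conservative adult-data policy).  Pupil values are
#' combined with the same rule.
#'
#' @param rec a [gaze_recording()].
#' @param include_single_eye keep samples where only one eye is valid?
#' @return A `gaze_trace` data.frame with columns `time`, `x`, `y`,
#'   `available`, `single_eye`, `interpolated`, `pupil`, and attributes
#'   `sampling_rate`.
#' @export
combine_eyes <- function(rec, include_single_eye = TRUE) {
  stopifnot(inherits(rec, "gaze_recording"))
  s <- rec$samples
  both <- s$left_valid & s$right_valid
  left_only <- s$left_valid & !s$right_valid
  right_only <- !s$left_valid & s$right_valid
  one <- (left_only | right_only) & include_single_eye

  n <- nrow(s)
  x <- rep(NA_real_, n); y <- rep(NA_real_, n); pupil <- rep(NA_real_, n)

  x[both] <- (s$left_x[both] + s$right_x[both]) / 2
  y[both] <- (s$left_y[both] + s$right_y[both]) / 2
  pupil[both] <- rowMeans(cbind(s$pupil_left[both], s$pupil_right[both]),
                          na.rm = TRUE)
  x[one & left_only] <- s$left_x[one & left_only]
  y[one & left_only] <- s$left_y[one & left_only]
  pupil[one & left_only] <- s$pupil_left[one & left_only]
  x[one & right_only] <- s$right_x[one & right_only]
  y[one & right_only] <- s$right_y[one & right_only]
  pupil[one & right_only] <- s$pupil_right[one & right_only]
  pupil[is.nan(pupil)] <- NA_real_

  trace <- data.frame(
    time = s$time, x = x, y = y,
    available = both | one,
    single_eye = one,
    interpolated = FALSE,
    pupil = pupil
  )
  attr(trace, "sampling_rate") <- rec$sampling_rate
  class(trace) <- c("gaze_trace", "data.frame")
  trace
}

trace_rate <- function(trace) {
  r <- attr(trace, "sampling_rate")
  if (is.null(r)) stop("trace lacks a sampling_rate attribute", call. = FALSE)
  r
}

#' Bilateral smoothing of a gaze trace
#'
#' Suppresses measurement jitter while preserving saccades.  Each
#' available sample is replaced by the weighted mean of the available
#' samples within `window` ms, the weight being the product of a temporal
#' Gaussian (sigma `temporal_sigma` ms) and a positional Gaussian on the
#' Euclidean distance in degrees (sigma `range_sigma` deg).  Because
#' samples across a saccade are many `range_sigma` away, their weight is
#' effectively zero and plateau positions are not dragged toward each
#' other.  Missing samples stay missing; the availability mask is never
#' changed.
#'
#' @param trace a `gaze_trace` from [combine_eyes()].
#' @param smoothing a [smoothing_params()] record.
#' @param dpp degrees per pixel.
#' @return The smoothed `gaze_trace`.
#' @export
bilateral_smooth <- function(trace, smoothing = smoothing_params(),
                             dpp = 0.0177) {
  stopifnot(inherits(smoothing, "smoothing_params"))
  n <- nrow(trace)
  dt <- 1000 / trace_rate(trace)
  W <- max(1L, as.integer(round(smoothing$window / dt)))
  x <- trace$x; y <- trace$y
  avail <- trace$available & !is.na(x) & !is.na(y)

  xs <- ifelse(avail, x, 0); ys <- ifelse(avail, y, 0)
  num_x <- ifelse(avail, x, 0)   # offset 0: weight 1
  num_y <- ifelse(avail, y, 0)
  den <- as.numeric(avail)
  two_ts2 <- 2 * smoothing$temporal_sigma^2
  two_rs2 <- 2 * smoothing$range_sigma^2

  for (k in seq_len(W)) {
    wt <- exp(-(k * dt)^2 / two_ts2)
    if (wt < 1e-12) break
    # neighbour at +k
    i <- seq_len(n - k)
    j <- i + k
    ok <- avail[i] & avail[j]
    d2 <- ((x[i] - x[j])^2 + (y[i] - y[j])^2) * dpp^2
    w <- ifelse(ok, wt * exp(-d2 / two_rs2), 0)
    w[is.na(w)] <- 0
    num_x[i] <- num_x[i] + w * xs[j]
    num_y[i] <- num_y[i] + w * ys[j]
    den[i] <- den[i] + w
    # neighbour at -k (same weights by symmetry of the kernel)
    num_x[j] <- num_x[j] + w * xs[i]
    num_y[j] <- num_y[j] + w * ys[i]
    den[j] <- den[j] + w
  }

  out <- trace
  out$x[avail] <- num_x[avail] / den[avail]
  out$y[avail] <- num_y[avail] / den[avail]
  out
}

#' Per-sample gaze velocity
#'
#' The forward intersample difference: `v[i]` is the Euclidean distance
#' between samples `i` and `i + 1` in pixels, converted to degrees and
#' multiplied by the sampling rate (deg/s).  The last sample copies its
#' predecessor's value; `v` is `NA` wherever either endpoint of the
#' difference is missing.
#'
#' @param trace a `gaze_trace` (normally smoothed).
#' @param dpp degrees per pixel.
#' @param sampling_rate sampling rate in Hz; defaults to the trace's own.
#' @return Numeric vector of velocities, one per sample.
#' @export
#' @examples
#' # 10 px between consecutive samples at 120 Hz, 0.0177 deg/px:
#' # v = 10 * 0.0177 * 120 = 21.24 deg/s
compute_velocity <- function(trace, dpp = 0.0177,
                             sampling_rate = trace_rate(trace)) {
  n <- nrow(trace)
  x <- trace$x; y <- trace$y
  x[!trace$available] <- NA_real_
  y[!trace$available] <- NA_real_
  v <- rep(NA_real_, n)
  if (n >= 2L) {
    d <- sqrt(diff(x)^2 + diff(y)^2)
    v[seq_len(n - 1L)] <- d * dpp * sampling_rate
    v[n] <- v[n - 1L]
  }
  v
}
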