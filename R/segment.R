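#' Segment a trace by velocity threshold
#'
#' Classic velocity-threshold event detection: every sample whose velocity
#' exceeds `velocity_threshold` is flagged saccadic, maximal runs of
#' missing samples are gaps, and the remaining maximal runs — the data
#' segments between saccades — are fixations.  Segments tile the
#' recording contiguously with half-open `[onset, offset)` intervals in
#' ms; a segment's offset is the next segment's onset (the last segment
#' closes one sample period after its final sample).
#'
#' @param trace a `gaze_trace`.
#' @param v velocity vector from [compute_velocity()], aligned with
#'   `trace`.  Available samples with undefined velocity (a missing
#'   neighbour) cannot be shown to be saccadic and fall to fixations.
#' @param velocity_threshold deg/s; strictly-greater comparison.
#' @return An `event_segmentation` data.frame with columns `label`
#'   (`"fixation"`, `"saccade"`, `"gap"`), `onset`, `offset` (ms), and the
#'   half-open sample index range `i0`, `i1` (`i1` inclusive).  A trace
#'   with no available samples yields a zero-row segmentation with a
#'   warning.
#' @export
segment_by_velocity <- function(trace, v, velocity_threshold) {
  stopifnot(length(v) == nrow(trace))
  if (!any(trace$available)) {
    warning("segment_by_velocity: no available samples; empty segmentation",
            call. = FALSE)
    return(empty_segmentation(trace))
  }
  labels <- ifelse(!trace$available, "gap",
                   ifelse(!is.na(v) & v > velocity_threshold,
                          "saccade", "fixation"))
  segmentation_from_labels(labels, trace)
}

empty_segmentation <- function(trace) {
  seg <- data.frame(label = character(), onset = numeric(),
                    offset = numeric(), i0 = integer(), i1 = integer(),
                    stringsAsFactors = FALSE)
  attr(seg, "sampling_rate") <- trace_rate(trace)
  class(seg) <- c("event_segmentation", "data.frame")
  seg
}

# run-length encode per-sample labels into tiling segments
segmentation_from_labels <- function(labels, trace) {
  r <- rle(labels)
  i1 <- cumsum(r$lengths)
  i0 <- i1 - r$lengths + 1L
  dt <- 1000 / trace_rate(trace)
  t <- trace$time
  onset <- t[i0]
  offset <- c(t[i0[-1]], t[length(t)] + dt)
  seg <- data.frame(label = r$values, onset = onset, offset = offset,
                    i0 = i0, i1 = i1, stringsAsFactors = FALSE)
  attr(seg, "sampling_rate") <- trace_rate(trace)
  class(seg) <- c("event_segmentation", "data.frame")
  seg
}

#' Interpolate short missing-data gaps inside fixations
#'
#' Missing-data gaps generate spurious velocity peaks that a
#' velocity-based detector mistakes for saccades, splitting one fixation
#' into several.  This pass fills only the gaps that can safely be assumed
#' to lie *within* a fixation, under two gates:
#'
#' * **latency gate** — the gap (span of missing samples) is at most
#'   `interpolation_latency` ms and both flanking segments are fixations;
#' * **displacement gate** — the Euclidean distance between the centroids
#'   of the two flanking fixations is below
#'   `max_interpolation_displacement` degrees (the eyes came back to where
#'   they were, so no saccade was hidden in the gap).
#'
#' Qualifying gaps are filled by linear interpolation between the last
#' available sample before and the first after; filled samples are marked
#' `interpolated = TRUE` and become available.  Gaps at the recording edge
#' are never filled.  Velocity must be recomputed by the caller
#' afterwards.
#'
#' @param trace a smoothed `gaze_trace`.
#' @param v velocity vector aligned with `trace` (pre-interpolation).
#' @param params a [detection_params()] record.
#' @return The trace with qualifying gaps filled; attribute
#'   `n_gaps_filled` counts them.
#' @export
interpolate_gaps <- function(trace, v, params) {
  stopifnot(inherits(params, "detection_params"))
  out <- trace
  n_filled <- 0L
  if (params$interpolation_latency <= 0) {
    attr(out, "n_gaps_filled") <- 0L
    return(out)
  }
  seg <- withCallingHandlers(
    segment_by_velocity(trace, v, params$velocity_threshold),
    warning = function(w) invokeRestart("muffleWarning")
  )
  if (nrow(seg) < 3L) {
    attr(out, "n_gaps_filled") <- 0L
    return(out)
  }
  dpp <- params$degrees_per_pixel
  for (k in which(seg$label == "gap")) {
    if (k == 1L || k == nrow(seg)) next          # edge gaps: no flank
    if (seg$offset[k] - seg$onset[k] > params$interpolation_latency) next
    if (seg$label[k - 1L] != "fixation" || seg$label[k + 1L] != "fixation")
      next
    cen <- function(s) {
      idx <- s$i0:s$i1
      idx <- idx[trace$available[idx]]
      c(mean(trace$x[idx]), mean(trace$y[idx]))
    }
    c1 <- cen(seg[k - 1L, ]); c2 <- cen(seg[k + 1L, ])
    if (sqrt(sum((c1 - c2)^2)) * dpp >= params$max_interpolation_displacement)
      next
    i0 <- seg$i0[k]; i1 <- seg$i1[k]
    a <- i0 - 1L; b <- i1 + 1L                  # flanking available samples
    idx <- i0:i1
    f <- (trace$time[idx] - trace$time[a]) /
         (trace$time[b] - trace$time[a])
    out$x[idx] <- out$x[a] + f * (out$x[b] - out$x[a])
    out$y[idx] <- out$y[a] + f * (out$y[b] - out$y[a])
    out$available[idx] <- TRUE
    out$interpolated[idx] <- TRUE
    n_filled <- n_filled + 1L
  }
  attr(out, "n_gaps_filled") <- n_filled
  out
}
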