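#' Intersample RMS of a sample sequence
#'
#' The root mean square of the Euclidean distances between consecutive
#' available samples, both axes together, in degrees — the standard
#' spatial-precision measure, here applied per fixation.  Fewer than two
#' available samples give 0.
#'
#' @param x,y pixel coordinates of the samples in one fixation (may
#'   contain `NA`; pairs with a missing endpoint are skipped).
#' @param dpp degrees per pixel.
#' @return RMS in degrees (>= 0).
#' @export
#' @examples
#' # samples alternating between two points d degrees apart have RMS = d
#' fixation_rms(c(0, 10, 0, 10), c(0, 0, 0, 0), dpp = 0.05)  # 0.5
fixation_rms <- function(x, y, dpp) {
  intersample_rms(x, y, dpp)
}

intersample_rms <- function(x, y, dpp) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) return(0)
  d2 <- (diff(x)^2 + diff(y)^2) * dpp^2
  sqrt(mean(d2))
}

#' Merge adjacent fixations close in time and space
#'
#' Low-precision data breaks fixations apart: single velocity peaks above
#' threshold get flagged as saccades and split one fixation into several.
#' This filter re-joins them: a fixation is merged with its successor iff
#' the interval between them is strictly less than `merge_max_gap` ms, the
#' centroid distance is at most `merge_max_distance` degrees, and no
#' missing-data sample lies between them (a data gap is handled by the
#' gated interpolation pass, never bridged here).  Merging is a greedy
#' left-to-right scan iterated to a fixed point, so a merged fixation can
#' merge again with its own successor.
#'
#' The merged fixation spans from the first onset to the second offset
#' (the bridged interval counts toward duration); its centroid, RMS, and
#' pupil mean are pooled over the member fixations' samples only.
#'
#' @param fixations a fixation data.frame (e.g. from
#'   [fixations_from_segmentation()]).  An optional logical column
#'   `gap_before` marks fixations separated from their predecessor by
#'   missing data; absent, all separators are considered mergeable.
#' @param merge_max_gap ms, strict `<`.
#' @param merge_max_distance degrees, inclusive `<=`.
#' @param dpp degrees per pixel (to measure centroid distance in degrees).
#' @return The fixation data.frame after merging; merged rows carry
#'   `merged = TRUE`.  Attribute `n_merges` counts merge operations.
#' @export
merge_adjacent <- function(fixations, merge_max_gap, merge_max_distance,
                           dpp) {
  df <- as_fixation_df_keep_gap(fixations)
  n_merges <- 0L
  repeat {
    merged_any <- FALSE
    i <- 1L
    while (i < nrow(df)) {
      gap <- df$onset[i + 1L] - df$offset[i]
      dist_deg <- sqrt((df$centroid_x[i + 1L] - df$centroid_x[i])^2 +
                       (df$centroid_y[i + 1L] - df$centroid_y[i])^2) * dpp
      if (gap < merge_max_gap && dist_deg <= merge_max_distance &&
          !isTRUE(df$gap_before[i + 1L])) {
        df[i, ] <- merge_pair(df[i, ], df[i + 1L, ], dpp)
        df <- df[-(i + 1L), , drop = FALSE]
        n_merges <- n_merges + 1L
        merged_any <- TRUE
        # stay at i: the merged fixation may merge with the next one
      } else {
        i <- i + 1L
      }
    }
    if (!merged_any) break
  }
  rownames(df) <- NULL
  df$id <- seq_len(nrow(df))
  attr(df, "n_merges") <- n_merges
  df
}

# pool two fixation rows; statistics over member samples only, duration
# spans the bridged interval
merge_pair <- function(a, b, dpp) {
  out <- a
  out$onset <- a$onset
  out$offset <- b$offset
  out$duration <- b$offset - a$onset
  na <- a$n_samples; nb <- b$n_samples
  out$n_samples <- na + nb
  out$centroid_x <- (na * a$centroid_x + nb * b$centroid_x) / (na + nb)
  out$centroid_y <- (na * a$centroid_y + nb * b$centroid_y) / (na + nb)
  # RMS over member-internal consecutive pairs, pooled by pair count
  pa <- max(na - 1L, 0L); pb <- max(nb - 1L, 0L)
  out$rms <- if (pa + pb > 0L) {
    sqrt((pa * a$rms^2 + pb * b$rms^2) / (pa + pb))
  } else 0
  out$n_interpolated <- a$n_interpolated + b$n_interpolated
  out$single_eye_fraction <-
    (na * a$single_eye_fraction + nb * b$single_eye_fraction) / (na + nb)
  wp <- c(if (!is.na(a$pupil_mean)) na else 0,
          if (!is.na(b$pupil_mean)) nb else 0)
  out$pupil_mean <- if (sum(wp) > 0) {
    sum(wp * c(a$pupil_mean, b$pupil_mean), na.rm = TRUE) / sum(wp)
  } else NA_real_
  out$merged <- TRUE
  out$gap_before <- a$gap_before
  out$centroid_x_deg <- out$centroid_x * dpp
  out$centroid_y_deg <- out$centroid_y * dpp
  out
}

#' Reject fixations by RMS precision
#'
#' Fixations whose intersample RMS is strictly above
#' `max_rms_per_fixation` degrees are moved to the rejected list with the
#' `rejected_rms` flag; a fixation whose RMS equals the threshold exactly
#' is kept.
#'
#' @param fixations fixation data.frame with `rms` filled.
#' @param max_rms_per_fixation degrees.
#' @return A list with `surviving` and `rejected` fixation data.frames.
#' @export
reject_by_rms <- function(fixations, max_rms_per_fixation) {
  bad <- fixations$rms > max_rms_per_fixation
  rejected <- fixations[bad, , drop = FALSE]
  if (nrow(rejected)) rejected$rejected_rms <- TRUE
  list(surviving = droprows(fixations, bad), rejected = rejected)
}

#' Reject fixations by minimum duration
#'
#' Fixations strictly shorter than `min_fixation_duration` ms are moved to
#' the rejected list with the `rejected_duration` flag; a fixation exactly
#' at the threshold is kept.
#'
#' @param fixations fixation data.frame.
#' @param min_fixation_duration ms.
#' @return A list with `surviving` and `rejected` fixation data.frames.
#' @export
reject_by_duration <- function(fixations, min_fixation_duration) {
  bad <- fixations$duration < min_fixation_duration
  rejected <- fixations[bad, , drop = FALSE]
  if (nrow(rejected)) rejected$rejected_duration <- TRUE
  list(surviving = droprows(fixations, bad), rejected = rejected)
}

droprows <- function(df, drop) {
  out <- df[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply the three post-hoc validation filters, in order
#'
#' Order matters and is fixed: (1) merge adjacent fixations close in
#' space and time, (2) reject fixations whose RMS exceeds the threshold,
#' (3) reject fixations shorter than the minimum duration.  Merging first
#' lets several short fragments of one true fixation survive the duration
#' filter as a single merged fixation that none of them would survive
#' alone.  Rejected fixations are kept in an audit list (with their
#' rejection flags) rather than discarded, supporting later manual
#' moderation.  The operation is idempotent.
#'
#' @param fixations a fixation data.frame, temporally ordered.
#' @param params a [detection_params()] record.
#' @return An object of class `fixation_set`: list with `surviving`,
#'   `rejected` (both fixation data.frames), `params`, and `counts`
#'   (named integer vector `merged`, `rms_rejected`, `duration_rejected`).
#' @export
posthoc_validate <- function(fixations, params) {
  stopifnot(inherits(params, "detection_params"))
  df <- as_fixation_df_keep_gap(fixations)
  merged <- merge_adjacent(df, params$merge_max_gap,
                           params$merge_max_distance,
                           params$degrees_per_pixel)
  n_merges <- attr(merged, "n_merges")
  r1 <- reject_by_rms(merged, params$max_rms_per_fixation)
  r2 <- reject_by_duration(r1$surviving, params$min_fixation_duration)
  rejected <- rbind(r1$rejected, r2$rejected)
  rejected <- rejected[order(rejected$onset), , drop = FALSE]
  rownames(rejected) <- NULL
  surviving <- r2$surviving
  surviving$id <- seq_len(nrow(surviving))
  structure(
    list(surviving = surviving, rejected = rejected, params = params,
         counts = c(merged = n_merges,
                    rms_rejected = nrow(r1$rejected),
                    duration_rejected = nrow(r2$rejected))),
    class = "fixation_set"
  )
}

as_fixation_df_keep_gap <- function(fixations) {
  gap <- fixations$gap_before
  df <- as_fixation_df(fixations)
  df$gap_before <- if (is.null(gap)) rep(FALSE, nrow(df)) else gap
  df
}

#' @export
print.fixation_set <- function(x, ...) {
  cat(sprintf("<fixation_set> %d surviving, %d rejected\n",
              nrow(x$surviving), nrow(x$rejected)))
  cat(sprintf("  merged: %d, rms-rejected: %d, duration-rejected: %d\n",
              x$counts[["merged"]], x$counts[["rms_rejected"]],
              x$counts[["duration_rejected"]]))
  if (nrow(x$surviving)) {
    cat(sprintf("  mean duration: %.1f ms\n", mean(x$surviving$duration)))
  }
  invisible(x)
}
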