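#' Normalized transcription activity from ROI measurements
#'
#' The puncta signal is the maximum intensity inside a small circular ROI
#' (ROI-1); the local background is the mean intensity of the surrounding
#' annulus (ROI-2, three times the ROI-1 radius, excluding ROI-1). The
#' normalized activity is \code{(roi1_max - roi2_mean) / roi2_mean}.
#' Because signal and background are divided, any multiplicative gain
#' applied to both -- photobleaching in particular -- cancels exactly.
#' When a punctum could not be identified, its "signal" is by convention
#' the local background, so the normalized value is 0.
#'
#' @param roi1_max max intensity inside the puncta circle, a.u.
#' @param roi2_mean mean background intensity in the annulus, a.u. (> 0).
#' @param identified logical; \code{FALSE} forces a value of 0.
#' @return normalized activity (dimensionless), vectorized.
#' @examples
#' normalized_intensity(300, 100)   # 2
#' @export
normalized_intensity <- function(roi1_max, roi2_mean, identified = TRUE) {
  if (any(!is.finite(roi2_mean)) || any(roi2_mean <= 0))
    stop("'roi2_mean' must be positive for a defined normalization",
         call. = FALSE)
  out <- (roi1_max - roi2_mean) / roi2_mean
  out[!identified] <- 0
  out
}

#' Signal-to-noise ratio of a punctum
#'
#' \code{(puncta_max - bg_mean) / bg_sd}: the background-subtracted peak
#' intensity in units of the background noise SD.
#'
#' @param puncta_max max intensity of the punctum, a.u.
#' @param bg_mean mean background intensity, a.u.
#' @param bg_sd SD of the background intensity, a.u. (> 0).
#' @return dimensionless SNR, vectorized.
#' @examples
#' snr(150, 50, 10)   # 10
#' @export
snr <- function(puncta_max, bg_mean, bg_sd) {
  if (any(!is.finite(bg_sd)) || any(bg_sd <= 0))
    stop("'bg_sd' must be > 0", call. = FALSE)
  (puncta_max - bg_mean) / bg_sd
}

#' Measure ROI intensity series from a spot movie
#'
#' For each frame and each punctum center, computes the ROI-1 maximum over
#' the inner disc and the mean and SD over the surrounding annulus (outer
#' radius three times the inner radius, inner disc excluded).
#'
#' @param movie a \code{spot_movie} or list of matrices.
#' @param centers data frame with columns \code{x}, \code{y} (pixel
#'   coordinates, 1-based).
#' @param roi1_diameter_um ROI-1 diameter in micrometres.
#' @param pixel_size_um pixel size in micrometres.
#' @return data frame with columns \code{spot}, \code{frame} (0-based),
#'   \code{roi1_max}, \code{roi2_mean}, \code{roi2_sd}.
#' @export
measure_movie <- function(movie, centers, roi1_diameter_um = 2.5,
                          pixel_size_um = 0.1) {
  frames <- if (inherits(movie, "spot_movie")) movie$frames else movie
  stopifnot(all(c("x", "y") %in% names(centers)))
  nr <- nrow(frames[[1]]); nc <- ncol(frames[[1]])
  r1 <- roi1_diameter_um / 2 / pixel_size_um
  r2 <- 3 * r1
  xs <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  ys <- matrix(rep(seq_len(nr), times = nc), nr, nc)
  out <- list()
  for (s in seq_len(nrow(centers))) {
    d2 <- (xs - centers$x[s])^2 + (ys - centers$y[s])^2
    inner <- d2 <= r1^2
    annulus <- d2 <= r2^2 & !inner
    if (centers$x[s] - r2 < 1 || centers$x[s] + r2 > nc ||
        centers$y[s] - r2 < 1 || centers$y[s] + r2 > nr)
      warning("ROI for spot ", s, " exceeds image bounds; clipped",
              call. = FALSE)
    if (!any(inner) || sum(annulus) < 2)
      stop("ROI for spot ", s, " has no usable pixels", call. = FALSE)
    for (f in seq_along(frames)) {
      img <- frames[[f]]
      out[[length(out) + 1L]] <- data.frame(
        spot = s, frame = f - 1L,
        roi1_max = max(img[inner]),
        roi2_mean = mean(img[annulus]),
        roi2_sd = sd(img[annulus]))
    }
  }
  do.call(rbind, out)
}

#' Detect transcription initiation in a normalized trace
#'
#' Initiation is the first time point at which the normalized intensity
#' exceeds the threshold for at least \code{min_consecutive} consecutive
#' points (the debounce guards against single-frame spikes). The default
#' threshold is self-calibrating: three times the median absolute
#' deviation of the trace's own baseline (points before \code{t0}, or the
#' first \code{baseline_points} points when none precede \code{t0}).
#'
#' Raising the threshold can only delay (or lose) the detected initiation,
#' never advance it.
#'
#' @param values normalized intensity series.
#' @param times matching time stamps, minutes (uniform grid).
#' @param threshold numeric threshold, or \code{"auto"}.
#' @param min_consecutive consecutive supra-threshold points required.
#' @param t0 cycle-start annotation, minutes (baseline is \code{t < t0}).
#' @param baseline_points fallback baseline length for \code{"auto"}.
#' @param min_auto floor for the automatic threshold, guarding against a
#'   perfectly flat (zero-MAD) baseline.
#' @return initiation time (minutes), or \code{NA} if never initiated.
#' @examples
#' tr <- c(0, 0, 0, 0.5, 2, 2, 2)
#' detect_initiation(tr, times = 0:6 * 5, threshold = 0.3)  # 15
#' @export
detect_initiation <- function(values, times, threshold = "auto",
                              min_consecutive = 2L, t0 = 0,
                              baseline_points = 5L, min_auto = 0.05) {
  if (!length(values)) stop("empty trace", call. = FALSE)
  stopifnot(length(values) == length(times))
  if (identical(threshold, "auto")) {
    base <- values[times < t0]
    if (length(base) < 3) base <- head(values, baseline_points)
    threshold <- max(3 * mad(base), min_auto)
  }
  above <- values > threshold
  run <- 0L
  for (i in seq_along(above)) {
    run <- if (above[i]) run + 1L else 0L
    if (run >= min_consecutive) return(times[i - min_consecutive + 1L])
  }
  NA_real_
}

#' Classify the activation pattern of an allele pair
#'
#' Partitions each cell into exactly one of four classes based on the two
#' alleles' initiation times: \code{"none"} (neither fires),
#' \code{"one_allele"}, \code{"same_time"} (both fire, absolute time
#' difference within \code{same_time_window}) or \code{"sequential"}.
#' There is no agreed numeric criterion for "at the same time"; the
#' default window is one sampling interval, and it is exposed so results
#' can be reported as a function of the window.
#'
#' @param t1,t2 initiation times of the alleles (minutes, \code{NA} =
#'   never fired).
#' @param same_time_window window (minutes) within which both alleles
#'   count as firing simultaneously.
#' @return list with \code{pattern}, \code{t1}, \code{t2} and
#'   \code{time_difference} (\code{NA} unless both fire).
#' @export
classify_activation <- function(t1, t2, same_time_window = 5) {
  both <- !is.na(t1) && !is.na(t2)
  pattern <- if (is.na(t1) && is.na(t2)) "none"
    else if (!both) "one_allele"
    else if (abs(t2 - t1) <= same_time_window) "same_time"
    else "sequential"
  list(pattern = pattern, t1 = t1, t2 = t2,
       time_difference = if (both) abs(t2 - t1) else NA_real_)
}

#' Activation records for a cohort of trace pairs
#'
#' Runs initiation detection on both alleles of every cell in a trace
#' table and classifies the activation pattern.
#'
#' @param traces trace table as produced by \code{\link{gen_trace_pairs}}
#'   (columns \code{cell_id}, \code{cycle}, \code{t_min}, \code{allele},
#'   either \code{normalized} or \code{roi1_max}/\code{roi2_mean}).
#' @param threshold,min_consecutive,t0 passed to
#'   \code{\link{detect_initiation}}.
#' @param same_time_window passed to \code{\link{classify_activation}}.
#' @return data frame with one row per cell: \code{cell_id}, \code{cycle},
#'   \code{t1}, \code{t2}, \code{pattern}, \code{time_difference}.
#' @export
activation_records <- function(traces, threshold = "auto",
                               min_consecutive = 2L, t0 = 0,
                               same_time_window = 5) {
  traces <- ensure_normalized(traces)
  out <- list()
  for (cid in unique(traces$cell_id)) {
    cell <- traces[traces$cell_id == cid, ]
    tinit <- vapply(1:2, function(a) {
      al <- cell[cell$allele == a, ]
      if (!nrow(al)) return(NA_real_)
      al <- al[order(al$t_min), ]
      detect_initiation(al$normalized, al$t_min, threshold = threshold,
                        min_consecutive = min_consecutive, t0 = t0)
    }, 0)
    cls <- classify_activation(tinit[1], tinit[2], same_time_window)
    out[[length(out) + 1L]] <- data.frame(
      cell_id = cid, cycle = cell$cycle[1], t1 = cls$t1, t2 = cls$t2,
      pattern = cls$pattern, time_difference = cls$time_difference,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# add a `normalized` column from ROI columns when absent
ensure_normalized <- function(traces) {
  if (!"normalized" %in% names(traces)) {
    stopifnot(all(c("roi1_max", "roi2_mean") %in% names(traces)))
    traces$normalized <- normalized_intensity(
      traces$roi1_max, traces$roi2_mean,
      identified = traces$identified %||% TRUE)
  }
  traces
}

#' Time for a trace to reach its plateau
#'
#' The trace is smoothed with a centred moving average and the plateau
#' time is the first time the smoothed trace reaches \code{fraction} of
#' its own maximum.
#'
#' @param values normalized intensity series.
#' @param times matching time stamps, minutes.
#' @param fraction plateau fraction of the smoothed maximum.
#' @param smooth_window moving-average window (points, odd).
#' @return plateau time in minutes, or \code{NA} for an all-zero trace.
#' @export
plateau_time <- function(values, times, fraction = 0.9,
                         smooth_window = 3L) {
  stopifnot(length(values) == length(times))
  sm <- moving_average(values, smooth_window)
  if (max(sm) <= 0) return(NA_real_)
  times[which(sm >= fraction * max(sm))[1]]
}

moving_average <- function(x, w) {
  if (w <= 1) return(x)
  half <- floor(w / 2)
  n <- length(x)
  vapply(seq_len(n), function(i)
    mean(x[max(1, i - half):min(n, i + half)]), 0)
}

#' Transcriptional-memory statistics for activation cohorts
#'
#' Summarizes inter-allele (or sister-cell) initiation-time differences
#' per group -- typically de novo transcription vs post-mitotic
#' re-activation -- and tests the two groups against each other with an
#' unpaired two-tailed t test. Faster, more synchronous re-activation
#' (a smaller mean difference) is the signature of transcriptional memory.
#'
#' @param records data frame from \code{\link{activation_records}} (needs
#'   \code{time_difference} and the grouping column).
#' @param group_col name of the grouping column (default \code{"cycle"}).
#' @return list with \code{per_group} (data frame: group, n, mean, sd) and
#'   \code{test} (the \code{htest} for the first two groups, or
#'   \code{NULL}).
#' @export
memory_statistics <- function(records, group_col = "cycle") {
  stopifnot(group_col %in% names(records),
            "time_difference" %in% names(records))
  rec <- records[!is.na(records$time_difference), ]
  groups <- unique(rec[[group_col]])
  per_group <- do.call(rbind, lapply(groups, function(g) {
    d <- rec$time_difference[rec[[group_col]] == g]
    data.frame(group = g, n = length(d), mean = mean(d),
               sd = if (length(d) >= 2) sd(d) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  test <- NULL
  if (length(groups) >= 2) {
    d1 <- rec$time_difference[rec[[group_col]] == groups[1]]
    d2 <- rec$time_difference[rec[[group_col]] == groups[2]]
    if (length(d1) >= 2 && length(d2) >= 2) {
      test <- if (sd(d1) == 0 && sd(d2) == 0) {
        # degenerate: both groups constant; equal means are
        # indistinguishable (p = 1), unequal means trivially distinct
        list(p.value = if (mean(d1) == mean(d2)) 1 else 0,
             estimate = c(mean(d1), mean(d2)),
             method = "degenerate comparison of constant groups")
      } else t.test(d1, d2, var.equal = FALSE)
    }
  }
  list(per_group = per_group, test = test)
}
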