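# Contraction statistics: deviation series, downward-peak counting,
# contraction strength (rate of change in body area) and frequency.

#' Mean-centred body-area deviation series
#'
#' Subtracts the average body area of the analysis window from each frame's
#' area: `deviation[t] = area[t] - mean(area)`. Downward peaks of this
#' signal are muscle contractions.
#'
#' @param series a [area_series()].
#' @return An object of class `wt_deviation` with fields `deviation_px2`,
#'   `mean_area_px2`, `frame_interval_s`, `n_frames`.
#' @export
deviation_series <- function(series) {
  stopifnot(inherits(series, "wt_area_series"))
  if (series$n_frames < 1L) stop("empty area series", call. = FALSE)
  m <- mean(series$area_px2)
  structure(list(deviation_px2 = series$area_px2 - m,
                 mean_area_px2 = m,
                 frame_interval_s = series$frame_interval_s,
                 n_frames = series$n_frames),
            class = "wt_deviation")
}

#' @export
print.wt_deviation <- function(x, ...) {
  cat(sprintf("<wt_deviation> %d frames, mean area %.4g px^2, range [%.4g, %.4g]\n",
              x$n_frames, x$mean_area_px2, min(x$deviation_px2), max(x$deviation_px2)))
  invisible(x)
}

# Plateau-aware run decomposition of a signal. A run is a maximal stretch of
# equal consecutive values; interior runs flanked by higher (lower)
# neighbours are local-minimum (local-maximum) runs. Series endpoints are
# never extrema. Representative index of a run is its centre (lower median).
signal_runs <- function(s) {
  r <- rle(s)
  n <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  rep_idx <- starts + (r$lengths - 1L) %/% 2L
  is_min <- is_max <- rep(FALSE, n)
  if (n >= 3L) {
    j <- 2:(n - 1L)
    is_min[j] <- r$values[j - 1L] > r$values[j] & r$values[j + 1L] > r$values[j]
    is_max[j] <- r$values[j - 1L] < r$values[j] & r$values[j + 1L] < r$values[j]
  }
  list(values = r$values, starts = starts, ends = ends, rep_idx = rep_idx,
       is_min = is_min, is_max = is_max)
}

# Topographic prominence of the local-minimum run `j` (on the inverted
# signal): on each side, walk to the nearest run with a strictly lower value
# (or the series end) and take the highest value encountered strictly
# between; the climb is that maximum minus the minimum's value. Prominence
# is the smaller of the two climbs.
run_prominence <- function(runs, j) {
  v <- runs$values
  n <- length(v)
  climb <- function(idx_range) {
    if (length(idx_range) == 0L) return(Inf)  # no room: treat as unbounded
    max(v[idx_range]) - v[j]
  }
  lower_left <- which(v[seq_len(j - 1L)] < v[j])
  a <- if (length(lower_left)) max(lower_left) + 1L else 1L
  left <- climb(a:(j - 1L))
  lower_right <- which(v[(j + 1L):n] < v[j]) + j
  b <- if (length(lower_right)) min(lower_right) - 1L else n
  right <- climb((j + 1L):b)
  min(left, right)
}

#' Detect contraction peaks in a deviation series
#'
#' The signal is optionally smoothed by a centred moving average; *lower
#' peaks* (contraction troughs) are local minima of the smoothed signal
#' whose topographic prominence is at least `min_prominence_px2`; *upper
#' peaks* are the local maxima between each adjacent pair of lower peaks,
#' plus a flanking local maximum before the first and after the last lower
#' peak where one exists. Series endpoints are never peaks. Peak positions
#' are indices of the smoothed extremum; reported values are taken from the
#' *unsmoothed* signal at those indices. Plateaus (runs of equal values)
#' count as a single extremum at the plateau centre; among tied flanking
#' maxima the one nearest the lower peak is taken.
#'
#' @param dev a [deviation_series()] (or a [area_series()], which is
#'   mean-centred first).
#' @param smooth_window_frames odd moving-average window (1 = no smoothing;
#'   default 3).
#' @param min_prominence_px2 prominence threshold in px^2; default
#'   (`NULL`) is 10% of the interquartile range of the deviation series.
#' @return An object of class `wt_peak_set`: `lower_peak_frames`,
#'   `upper_peak_frames` (1-based, strictly increasing, alternating when
#'   merged), `lower_peak_values`, `upper_peak_values` (unsmoothed px^2),
#'   `prominences`, and the parameters used.
#' @export
detect_peaks <- function(dev, smooth_window_frames = 3L, min_prominence_px2 = NULL) {
  if (inherits(dev, "wt_area_series")) dev <- deviation_series(dev)
  stopifnot(inherits(dev, "wt_deviation"))
  x <- dev$deviation_px2
  w <- as.integer(smooth_window_frames)
  if (w < 1L || w %% 2L == 0L)
    stop("`smooth_window_frames` must be odd and >= 1", call. = FALSE)
  if (w > length(x)) stop("smoothing window longer than the series", call. = FALSE)
  if (is.null(min_prominence_px2)) min_prominence_px2 <- 0.1 * IQR(x)
  stop_if_not_scalar_number(min_prominence_px2, "min_prominence_px2", 0)

  s <- moving_average(x, w)
  runs <- signal_runs(s)

  min_runs <- which(runs$is_min)
  keep <- min_runs[vapply(min_runs, function(j)
    run_prominence(runs, j) >= min_prominence_px2, logical(1))]
  lows <- runs$rep_idx[keep]
  prom <- vapply(keep, function(j) run_prominence(runs, j), numeric(1))

  uppers <- integer()
  if (length(lows) >= 1L) {
    max_runs <- which(runs$is_max)
    # one maximum strictly between each adjacent pair of lower peaks
    if (length(lows) >= 2L) {
      for (k in seq_len(length(lows) - 1L)) {
        a <- lows[k]; b <- lows[k + 1L]
        win <- (a + 1L):(b - 1L)
        m <- max(s[win])
        idxs <- win[s[win] == m]
        uppers <- c(uppers, idxs[(length(idxs) + 1L) %/% 2L])
      }
    }
    # flanking maxima (genuine interior local maxima only)
    lead <- max_runs[runs$rep_idx[max_runs] < lows[1L]]
    if (length(lead)) {
      best <- max(runs$values[lead])
      cand <- lead[runs$values[lead] == best]
      uppers <- c(uppers, runs$rep_idx[max(cand)])  # nearest the first trough
    }
    trail <- max_runs[runs$rep_idx[max_runs] > lows[length(lows)]]
    if (length(trail)) {
      best <- max(runs$values[trail])
      cand <- trail[runs$values[trail] == best]
      uppers <- c(uppers, runs$rep_idx[min(cand)])
    }
    uppers <- sort(uppers)
  }

  structure(list(lower_peak_frames = as.integer(lows),
                 upper_peak_frames = as.integer(uppers),
                 lower_peak_values = x[lows],
                 upper_peak_values = x[uppers],
                 prominences = prom,
                 smooth_window_frames = w,
                 min_prominence_px2 = min_prominence_px2,
                 n_frames = length(x)),
            class = "wt_peak_set")
}

#' @export
print.wt_peak_set <- function(x, ...) {
  cat(sprintf("<wt_peak_set> %d lower / %d upper peaks over %d frames (window %d, prominence >= %.3g px^2)\n",
              length(x$lower_peak_frames), length(x$upper_peak_frames),
              x$n_frames, x$smooth_window_frames, x$min_prominence_px2))
  invisible(x)
}

#' Contraction count, strength and frequency from a peak set
#'
#' The number of downward (lower) peaks is the number of contractions. Each
#' contraction's amplitude is the deviation value of the nearest preceding
#' upper peak (the window's first sample if the leading trough has none)
#' minus the lower-peak value. The *rate of change in body area* is the mean
#' of these peak-to-trough excursions (`amplitude_mode = "mean_excursion"`,
#' the default; `"excursion_over_n"` additionally divides by the contraction
#' count, retained for sensitivity analysis). Contraction frequency is
#' `n_contractions / (n_analysis_frames * frame_interval_s)`.
#'
#' @param dev the [deviation_series()] the peaks were detected on.
#' @param peaks a [detect_peaks()] result for `dev`.
#' @param amplitude_mode see Description.
#' @return An object of class `wt_contraction`: `n_contractions`,
#'   `amplitudes_px2`, `rate_of_change_px2` (`NA` with
#'   `rate_undefined = TRUE` when no contraction was detected),
#'   `frequency_hz`, `n_analysis_frames`, `frame_interval_s`, `peaks`.
#' @export
contraction_metrics <- function(dev, peaks,
                                amplitude_mode = c("mean_excursion", "excursion_over_n")) {
  stopifnot(inherits(dev, "wt_deviation"), inherits(peaks, "wt_peak_set"))
  amplitude_mode <- match.arg(amplitude_mode)
  if (peaks$n_frames != dev$n_frames)
    stop("`peaks` was not derived from `dev` (frame count mismatch)", call. = FALSE)
  x <- dev$deviation_px2
  lows <- peaks$lower_peak_frames
  n <- length(lows)
  if (n == 0L) {
    res <- list(n_contractions = 0L, amplitudes_px2 = numeric(),
                rate_of_change_px2 = NA_real_, rate_undefined = TRUE,
                frequency_hz = 0,
                n_analysis_frames = dev$n_frames,
                frame_interval_s = dev$frame_interval_s,
                amplitude_mode = amplitude_mode, peaks = peaks)
    return(structure(res, class = "wt_contraction"))
  }
  amp <- vapply(lows, function(p) {
    prev <- peaks$upper_peak_frames[peaks$upper_peak_frames < p]
    ref <- if (length(prev)) x[max(prev)] else x[1L]
    ref - x[p]
  }, numeric(1))
  rate <- mean(amp)
  if (amplitude_mode == "excursion_over_n") rate <- rate / n
  structure(list(n_contractions = n,
                 amplitudes_px2 = amp,
                 rate_of_change_px2 = rate,
                 rate_undefined = FALSE,
                 frequency_hz = n / (dev$n_frames * dev$frame_interval_s),
                 n_analysis_frames = dev$n_frames,
                 frame_interval_s = dev$frame_interval_s,
                 amplitude_mode = amplitude_mode,
                 peaks = peaks),
            class = "wt_contraction")
}

#' @export
print.wt_contraction <- function(x, ...) {
  cat("Body-wall muscle contraction assay\n")
  cat(sprintf("  analysis window : %d frames at %.3g s/frame (%.2f s)\n",
              x$n_analysis_frames, x$frame_interval_s,
              x$n_analysis_frames * x$frame_interval_s))
  cat(sprintf("  contractions    : %d\n", x$n_contractions))
  cat(sprintf("  rate of change  : %s px^2\n",
              if (x$rate_undefined) "undefined (no contraction)"
              else format(x$rate_of_change_px2, digits = 4)))
  cat(sprintf("  frequency       : %.4g /s\n", x$frequency_hz))
  invisible(x)
}

#' @export
summary.wt_contraction <- function(object, ...) {
  d <- data.frame(n_contractions = object$n_contractions,
                  rate_of_change_px2 = object$rate_of_change_px2,
                  frequency_hz = object$frequency_hz,
                  n_analysis_frames = object$n_analysis_frames)
  if (object$n_contractions > 0) {
    d$amplitude_min_px2 <- min(object$amplitudes_px2)
    d$amplitude_max_px2 <- max(object$amplitudes_px2)
  }
  d
}

#' Contraction analysis of a precomputed area series
#'
#' Deviation series, peak detection and contraction metrics in one step —
#' no segmentation or QC; the whole series is the analysis window.
#'
#' @inheritParams detect_peaks
#' @inheritParams contraction_metrics
#' @param series a [area_series()].
#' @return A `wt_contraction` (see [contraction_metrics()]).
#' @export
analyze_area_series <- function(series, smooth_window_frames = 3L,
                                min_prominence_px2 = NULL,
                                amplitude_mode = c("mean_excursion", "excursion_over_n")) {
  dev <- deviation_series(series)
  peaks <- detect_peaks(dev, smooth_window_frames, min_prominence_px2)
  contraction_metrics(dev, peaks, amplitude_mode = amplitude_mode)
}

#' Full contraction assay on a movie
#'
#' Composition of the whole measurement chain: [segment_worm()] ->
#' [qc_full_body()] -> [area_per_frame()] (cropped to the longest eligible
#' full-body run) -> [deviation_series()] -> [detect_peaks()] ->
#' [contraction_metrics()]. An ineligible movie (no full-body run strictly
#' longer than `min_run_seconds`) is an error naming the failed filter.
#'
#' @inheritParams segment_worm
#' @inheritParams detect_peaks
#' @inheritParams contraction_metrics
#' @param min_run_seconds QC eligibility bound (default 3 s, strict `>`).
#' @return A `wt_contraction` with an additional `provenance` element
#'   recording the analysis window, thresholds and parameters.
#' @export
run_contraction_assay <- function(stack, method = c("otsu", "fixed"),
                                  fixed_threshold = NULL, min_object_px = 20L,
                                  min_run_seconds = 3,
                                  smooth_window_frames = 3L,
                                  min_prominence_px2 = NULL,
                                  amplitude_mode = c("mean_excursion", "excursion_over_n")) {
  method <- match.arg(method)
  amplitude_mode <- match.arg(amplitude_mode)
  masks <- segment_worm(stack, method, fixed_threshold, min_object_px)
  qc <- qc_full_body(masks, min_seconds = min_run_seconds)
  if (!qc$eligible)
    stop(sprintf(paste0("movie failed the full-body QC filter: longest continuous ",
                        "full-body capture is %.3g s (%d frames), not > %g s"),
                 qc$run_seconds, qc$longest_run_frames, min_run_seconds),
         call. = FALSE)
  win <- qc$run_start:qc$run_end
  series <- area_series(masks$area_px2[win], stack$frame_interval_s)
  res <- analyze_area_series(series, smooth_window_frames, min_prominence_px2,
                             amplitude_mode)
  res$provenance <- list(run_start = qc$run_start, run_end = qc$run_end,
                         run_seconds = qc$run_seconds,
                         threshold_method = method,
                         fixed_threshold = fixed_threshold,
                         min_object_px = min_object_px,
                         min_run_seconds = min_run_seconds,
                         smooth_window_frames = res$peaks$smooth_window_frames,
                         min_prominence_px2 = res$peaks$min_prominence_px2,
                         amplitude_mode = amplitude_mode)
  res
}
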