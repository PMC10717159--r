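# Fluorescence quantification: nuclei counting (difference-of-Gaussians +
# peak picking) and whole-body background-subtracted intensity.

#' Count fluorescent nuclei in a muscle bundle image
#'
#' Band-pass filters the image with a difference of Gaussians over
#' `blob_sigma_range`, then picks local maxima of the response: a candidate
#' pixel must be the maximum of its `min_peak_distance`-radius neighbourhood
#' and its response must be at least `rel_threshold` times the maximum
#' response; candidates are then greedily pruned (strongest first) so that
#' retained centres are pairwise at least `min_peak_distance` apart. The
#' supplied image is taken as the (pre-cropped) bundle region; no bundle
#' delineation is attempted. A constant image has zero count.
#'
#' @param img a [fluorescence_image()].
#' @param blob_sigma_range length-2 numeric, the small and large Gaussian
#'   SDs of the band-pass (pixels); spots of SD between the two respond
#'   strongest.
#' @param min_peak_distance_px minimum separation between detected centres.
#' @param rel_threshold response threshold relative to the maximum
#'   band-pass response (0-1).
#' @return An object of class `wt_nuclei_count`: `n_nuclei`, `centers`
#'   (n x 2 matrix of (row, col)), and the detection parameters.
#' @export
count_nuclei <- function(img, blob_sigma_range = c(1.5, 3),
                         min_peak_distance_px = 5, rel_threshold = 0.1) {
  stopifnot(inherits(img, "wt_fluor_image"))
  stopifnot(length(blob_sigma_range) == 2L, all(blob_sigma_range > 0),
            blob_sigma_range[1] < blob_sigma_range[2],
            min_peak_distance_px > 0, rel_threshold > 0, rel_threshold <= 1)
  x <- img$image
  empty <- function() structure(list(n_nuclei = 0L,
                                     centers = matrix(numeric(), 0L, 2L),
                                     blob_sigma_range = blob_sigma_range,
                                     min_peak_distance_px = min_peak_distance_px,
                                     rel_threshold = rel_threshold),
                                class = "wt_nuclei_count")
  if (diff(range(x)) == 0) return(empty())

  dog <- EBImage::imageData(EBImage::gblur(x, sigma = blob_sigma_range[1])) -
         EBImage::imageData(EBImage::gblur(x, sigma = blob_sigma_range[2]))
  mx <- max(dog)
  if (mx <= 0) return(empty())

  # local maxima within a square neighbourhood of radius min_peak_distance
  rad <- as.integer(ceiling(min_peak_distance_px))
  H <- nrow(dog); W <- ncol(dog)
  padded <- matrix(-Inf, H + 2L * rad, W + 2L * rad)
  padded[rad + seq_len(H), rad + seq_len(W)] <- dog
  neigh_max <- matrix(-Inf, H, W)
  for (dr in -rad:rad) for (dc in -rad:rad) {
    if (dr == 0L && dc == 0L) next
    neigh_max <- pmax(neigh_max,
                      padded[rad + dr + seq_len(H), rad + dc + seq_len(W)])
  }
  cand <- which(dog > neigh_max & dog >= rel_threshold * mx)
  if (length(cand) == 0L) return(empty())
  cr <- (cand - 1L) %% H + 1L
  cc <- (cand - 1L) %/% H + 1L
  o <- order(dog[cand], decreasing = TRUE)
  cr <- cr[o]; cc <- cc[o]
  keep_r <- integer(); keep_c <- integer()
  for (i in seq_along(cr)) {
    if (length(keep_r) == 0L ||
        all((keep_r - cr[i])^2 + (keep_c - cc[i])^2 >= min_peak_distance_px^2)) {
      keep_r <- c(keep_r, cr[i]); keep_c <- c(keep_c, cc[i])
    }
  }
  ord <- order(keep_r, keep_c)
  centers <- cbind(row = keep_r[ord], col = keep_c[ord])
  structure(list(n_nuclei = nrow(centers), centers = centers,
                 blob_sigma_range = blob_sigma_range,
                 min_peak_distance_px = min_peak_distance_px,
                 rel_threshold = rel_threshold),
            class = "wt_nuclei_count")
}

#' @export
print.wt_nuclei_count <- function(x, ...) {
  cat(sprintf("Detected %d nuclei (DoG sigma %.3g-%.3g px, min separation %.3g px)\n",
              x$n_nuclei, x$blob_sigma_range[1], x$blob_sigma_range[2],
              x$min_peak_distance_px))
  invisible(x)
}

#' Whole-body background-subtracted fluorescence intensity
#'
#' The body is the largest 8-connected component above an intensity
#' threshold (Otsu by default). The background level is a statistic of the
#' non-body pixels — their intensity mode (default) or a low percentile.
#' The integrated intensity is the sum over body pixels of
#' `max(pixel - background, 0)`; the mean intensity is integrated / area.
#'
#' @param img a [fluorescence_image()].
#' @param body_threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_threshold threshold for `"fixed"`.
#' @param background_method `"mode"` or `"percentile"`.
#' @param pct percentile (0-100) for `background_method = "percentile"`.
#' @return An object of class `wt_intensity`: `integrated_intensity`,
#'   `mean_intensity`, `body_area_px2`, `background_level`,
#'   `threshold_used`, `body_mask`.
#' @export
total_intensity <- function(img, body_threshold_method = c("otsu", "fixed"),
                            fixed_threshold = NULL,
                            background_method = c("mode", "percentile"), pct = 5) {
  stopifnot(inherits(img, "wt_fluor_image"))
  body_threshold_method <- match.arg(body_threshold_method)
  background_method <- match.arg(background_method)
  x <- img$image
  th <- if (body_threshold_method == "otsu") otsu_threshold(x) else {
    stop_if_not_scalar_number(fixed_threshold, "fixed_threshold")
    fixed_threshold
  }
  mask <- if (is.na(th)) matrix(FALSE, nrow(x), ncol(x)) else largest_component(x > th)
  area <- sum(mask)
  if (area == 0L) stop("empty body mask: no foreground above threshold", call. = FALSE)
  bg_px <- x[!mask]
  background <- if (length(bg_px) == 0L) 0
    else if (background_method == "mode") intensity_mode(bg_px)
    else unname(quantile(bg_px, pct / 100))
  integrated <- sum(pmax(x[mask] - background, 0))
  structure(list(integrated_intensity = integrated,
                 mean_intensity = integrated / area,
                 body_area_px2 = area,
                 background_level = background,
                 background_method = background_method,
                 threshold_used = th),
            class = "wt_intensity")
}

#' @export
print.wt_intensity <- function(x, ...) {
  cat(sprintf(paste0("Whole-body fluorescence: integrated %.6g (mean %.4g over ",
                     "%d px^2 body; background %.4g by %s)\n"),
              x$integrated_intensity, x$mean_intensity, x$body_area_px2,
              x$background_level, x$background_method))
  invisible(x)
}
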