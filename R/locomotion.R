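# Movement-trace area assay: area covered by a worm's track on a plate
# photograph.

#' Track image container
#'
#' A grayscale plate photograph of a single worm's movement trace with a
#' declared polarity. Tracks carved into a bacterial lawn are dark on a
#' light background (the default).
#'
#' @param image numeric matrix of pixel intensities.
#' @param polarity `"dark_trace_on_light"` or `"light_trace_on_dark"`.
#' @param pixel_scale_mm optional mm per pixel, for areas in mm^2.
#' @return An object of class `wt_track_image`.
#' @export
track_image <- function(image, polarity = c("dark_trace_on_light", "light_trace_on_dark"),
                        pixel_scale_mm = NULL) {
  check_image_matrix(image)
  polarity <- match.arg(polarity)
  if (!is.null(pixel_scale_mm))
    stop_if_not_scalar_number(pixel_scale_mm, "pixel_scale_mm", 0, strict_min = TRUE)
  structure(list(image = image, polarity = polarity, pixel_scale_mm = pixel_scale_mm),
            class = "wt_track_image")
}

#' @export
print.wt_track_image <- function(x, ...) {
  cat(sprintf("<wt_track_image> %d x %d px, %s%s\n", nrow(x$image), ncol(x$image),
              x$polarity,
              if (is.null(x$pixel_scale_mm)) "" else
                sprintf(", %.4g mm/px", x$pixel_scale_mm)))
  invisible(x)
}

#' Read a track image from TIFF or PNG
#'
#' RGB(A) images are converted to grayscale by channel averaging (colour
#' channels only).
#'
#' @inheritParams track_image
#' @param path image path (`.tif`, `.tiff` or `.png`).
#' @return A [track_image()].
#' @export
read_track_image <- function(path, polarity = c("dark_trace_on_light", "light_trace_on_dark"),
                             pixel_scale_mm = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
         else tiff::readTIFF(path)
  if (length(dim(img)) == 3L) {
    nch <- min(dim(img)[3], 3L)
    img <- apply(img[, , seq_len(nch), drop = FALSE], c(1, 2), mean)
  }
  track_image(img, polarity, pixel_scale_mm)
}

#' Quantify the area covered by a movement trace
#'
#' The image is binarized toward the declared trace polarity (Otsu by
#' default, or a fixed intensity threshold), connected components smaller
#' than `min_component_px` are removed as dust, and the remaining foreground
#' pixel count is the trace area. A constant (blank) image has area 0.
#'
#' @param img a [track_image()].
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_threshold intensity cut for `method = "fixed"`; pixels on
#'   the trace side of it (below for dark traces, above for light) are
#'   foreground.
#' @param min_component_px speck-removal size (default 25 px).
#' @return An object of class `wt_movement_result`: `trace_area_px2`,
#'   `trace_area_mm2` (when a pixel scale is set), `threshold_used`, and the
#'   binary `trace_mask`.
#' @export
quantify_track_area <- function(img, method = c("otsu", "fixed"),
                                fixed_threshold = NULL, min_component_px = 25L) {
  stopifnot(inherits(img, "wt_track_image"))
  method <- match.arg(method)
  x <- img$image
  if (img$polarity == "dark_trace_on_light") x <- -x  # trace is always "bright" internally
  if (method == "fixed") {
    stop_if_not_scalar_number(fixed_threshold, "fixed_threshold")
    rng <- range(img$image)
    if (fixed_threshold < rng[1] || fixed_threshold > rng[2])
      stop(sprintf("fixed_threshold %g outside intensity range [%g, %g]",
                   fixed_threshold, rng[1], rng[2]), call. = FALSE)
    th <- if (img$polarity == "dark_trace_on_light") -fixed_threshold else fixed_threshold
  } else {
    th <- otsu_threshold(x)
  }
  if (is.na(th)) {
    mask <- matrix(FALSE, nrow(x), ncol(x))  # constant image: no trace
  } else {
    mask <- remove_small_components(x > th, min_component_px)
  }
  area <- sum(mask)
  structure(list(trace_area_px2 = area,
                 trace_area_mm2 = if (is.null(img$pixel_scale_mm)) NULL
                                  else area * img$pixel_scale_mm^2,
                 threshold_used = if (is.na(th)) NA_real_
                                  else if (img$polarity == "dark_trace_on_light") -th else th,
                 min_component_px = min_component_px,
                 trace_mask = mask),
            class = "wt_movement_result")
}

#' @export
print.wt_movement_result <- function(x, ...) {
  cat(sprintf("Movement-trace area: %g px^2%s (threshold %.4g, specks < %d px removed)\n",
              x$trace_area_px2,
              if (is.null(x$trace_area_mm2)) "" else sprintf(" = %.4g mm^2", x$trace_area_mm2),
              x$threshold_used, x$min_component_px))
  invisible(x)
}
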