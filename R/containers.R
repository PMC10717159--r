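# Core data containers of the contraction assay.

#' Frame stack: an ordered grayscale movie
#'
#' A movie is a list of equally sized numeric matrices (frames) recorded at
#' a fixed frame interval. The contraction assay default interval is 0.07 s
#' per frame.
#'
#' @param frames list of numeric matrices, all with identical dimensions.
#' @param frame_interval_s seconds between consecutive frames (> 0).
#' @return An object of class `wt_frame_stack`.
#' @export
frame_stack <- function(frames, frame_interval_s = 0.07) {
  if (is.array(frames) && length(dim(frames)) == 3L)
    frames <- lapply(seq_len(dim(frames)[3]), function(t) frames[, , t])
  stopifnot(is.list(frames), length(frames) >= 1L)
  d <- dim(frames[[1]])
  for (f in frames) {
    if (!is.matrix(f) || !identical(dim(f), d))
      stop("all frames must be matrices with identical dimensions", call. = FALSE)
  }
  stop_if_not_scalar_number(frame_interval_s, "frame_interval_s", 0, strict_min = TRUE)
  structure(list(frames = frames, frame_interval_s = frame_interval_s),
            class = "wt_frame_stack")
}

#' @export
print.wt_frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<wt_frame_stack> %d frames of %d x %d px, %.3g s/frame (%.2f s)\n",
              length(x$frames), d[1], d[2], x$frame_interval_s,
              length(x$frames) * x$frame_interval_s))
  invisible(x)
}

#' @export
length.wt_frame_stack <- function(x) length(x$frames)

#' Read a multi-page TIFF movie as a frame stack
#'
#' @param path path to a multi-page grayscale TIFF.
#' @param frame_interval_s recording interval in seconds.
#' @return A [frame_stack()].
#' @export
read_frame_stack <- function(path, frame_interval_s = 0.07) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # first channel of RGB(A)
    p
  })
  frame_stack(pages, frame_interval_s)
}

#' Write a frame stack as a multi-page TIFF
#'
#' Intensities are clipped to `[0, 1]` (32-bit float storage).
#'
#' @param stack a [frame_stack()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path) {
  stopifnot(inherits(stack, "wt_frame_stack"))
  frames <- lapply(stack$frames, function(f) pmin(pmax(f, 0), 1))
  tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  invisible(path)
}

#' Per-frame body-area series
#'
#' The signal on which all contraction statistics are computed: worm body
#' area, in squared pixels, for each frame of the analysis window.
#'
#' @param area_px2 numeric vector of per-frame areas (>= 0).
#' @param frame_interval_s seconds between frames (> 0).
#' @return An object of class `wt_area_series` with fields `area_px2`,
#'   `frame_interval_s` and `n_frames`.
#' @export
area_series <- function(area_px2, frame_interval_s = 0.07) {
  stopifnot(is.numeric(area_px2), length(area_px2) >= 1L)
  if (any(!is.finite(area_px2)) || any(area_px2 < 0))
    stop("`area_px2` must be finite and >= 0", call. = FALSE)
  stop_if_not_scalar_number(frame_interval_s, "frame_interval_s", 0, strict_min = TRUE)
  structure(list(area_px2 = as.numeric(area_px2),
                 frame_interval_s = frame_interval_s,
                 n_frames = length(area_px2)),
            class = "wt_area_series")
}

#' @export
print.wt_area_series <- function(x, ...) {
  cat(sprintf("<wt_area_series> %d frames at %.3g s/frame; area %.4g-%.4g px^2 (mean %.4g)\n",
              x$n_frames, x$frame_interval_s, min(x$area_px2), max(x$area_px2),
              mean(x$area_px2)))
  invisible(x)
}

#' @export
as.data.frame.wt_area_series <- function(x, ...) {
  data.frame(frame = seq_len(x$n_frames),
             time_s = (seq_len(x$n_frames) - 1) * x$frame_interval_s,
             area_px2 = x$area_px2)
}

#' @export
plot.wt_area_series <- function(x, ...) {
  d <- as.data.frame(x)
  plot(d$time_s, d$area_px2, type = "l", xlab = "time (s)",
       ylab = expression(body ~ area ~ (px^2)), ...)
  abline(h = mean(d$area_px2), lty = 2, col = "grey40")
  invisible(x)
}

#' Write / read an area series as CSV
#'
#' The CSV has columns `frame`, `time_s`, `area_px2`.
#'
#' @param series a [area_series()].
#' @param path CSV path.
#' @return `path` (write) or a [area_series()] (read).
#' @export
write_area_series <- function(series, path) {
  stopifnot(inherits(series, "wt_area_series"))
  write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_area_series
#' @param frame_interval_s interval override; by default inferred from the
#'   `time_s` column.
#' @export
read_area_series <- function(path, frame_interval_s = NULL) {
  d <- read.csv(path)
  if (!all(c("area_px2") %in% names(d)))
    stop("CSV must contain an `area_px2` column", call. = FALSE)
  if (is.null(frame_interval_s)) {
    if ("time_s" %in% names(d) && nrow(d) > 1)
      frame_interval_s <- diff(d$time_s[1:2])
    else frame_interval_s <- 0.07
  }
  area_series(d$area_px2, frame_interval_s)
}
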