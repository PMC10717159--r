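# Movie -> per-frame body area, plus the movie eligibility (QC) filter.

#' Segment the worm in every frame of a movie
#'
#' Per frame, pixels strictly above an intensity threshold are candidate
#' foreground; only the largest 8-connected component of size at least
#' `min_object_px` is retained (anything smaller, e.g. debris, is dropped,
#' and an empty mask — area 0 — is allowed). The default threshold is Otsu's
#' method computed per frame; a fixed threshold can be supplied instead for
#' reproducible overrides.
#'
#' @param stack a [frame_stack()].
#' @param method `"otsu"` (per-frame, parameter free) or `"fixed"`.
#' @param fixed_threshold intensity threshold for `method = "fixed"`; must
#'   lie within the intensity range of the stack.
#' @param min_object_px minimum component size in pixels (default 20).
#' @return An object of class `wt_mask_stack`: list of logical masks,
#'   per-frame pixel counts, and the frame interval.
#' @export
segment_worm <- function(stack, method = c("otsu", "fixed"),
                         fixed_threshold = NULL, min_object_px = 20L) {
  stopifnot(inherits(stack, "wt_frame_stack"))
  method <- match.arg(method)
  for (f in stack$frames) check_image_matrix(f, "frame")
  if (method == "fixed") {
    rng <- range(vapply(stack$frames, range, numeric(2)))
    stop_if_not_scalar_number(fixed_threshold, "fixed_threshold")
    if (fixed_threshold < rng[1] || fixed_threshold > rng[2])
      stop(sprintf("fixed_threshold %g outside intensity range [%g, %g]",
                   fixed_threshold, rng[1], rng[2]), call. = FALSE)
  }
  masks <- lapply(stack$frames, function(f) {
    th <- if (method == "otsu") otsu_threshold(f) else fixed_threshold
    if (is.na(th)) return(matrix(FALSE, nrow(f), ncol(f)))  # constant frame
    largest_component(f > th, min_px = min_object_px)
  })
  structure(list(masks = masks,
                 area_px2 = vapply(masks, sum, numeric(1)),
                 frame_interval_s = stack$frame_interval_s,
                 method = method,
                 fixed_threshold = fixed_threshold,
                 min_object_px = min_object_px),
            class = "wt_mask_stack")
}

#' @export
print.wt_mask_stack <- function(x, ...) {
  cat(sprintf("<wt_mask_stack> %d masks, area %g-%g px^2, method=%s\n",
              length(x$masks), min(x$area_px2), max(x$area_px2), x$method))
  invisible(x)
}

#' Per-frame body area from a mask stack
#'
#' @param masks a `wt_mask_stack` from [segment_worm()].
#' @param frame_interval_s optional interval override.
#' @return A [area_series()]: `area_px2[t]` is the foreground pixel count of
#'   frame `t`.
#' @export
area_per_frame <- function(masks, frame_interval_s = NULL) {
  stopifnot(inherits(masks, "wt_mask_stack"))
  area_series(masks$area_px2, frame_interval_s %||% masks$frame_interval_s)
}

#' Movie eligibility filter: continuous full-body capture
#'
#' A frame is "full body" iff its mask is nonempty and touches no image
#' border. A movie is eligible iff its longest run of consecutive full-body
#' frames lasts strictly more than `min_seconds` (default 3 s, the assay's
#' inclusion rule). The longest run is returned so downstream statistics can
#' be computed on that contiguous window only.
#'
#' @param masks a `wt_mask_stack` from [segment_worm()].
#' @param frame_interval_s optional interval override.
#' @param min_seconds eligibility bound in seconds (strict `>`).
#' @return A list: `eligible` (logical), `longest_run_frames`,
#'   `run_start`, `run_end` (1-based frame indices, `NA` if no full-body
#'   frame), `run_seconds`, and the per-frame logical `full_body`.
#' @export
qc_full_body <- function(masks, frame_interval_s = NULL, min_seconds = 3) {
  stopifnot(inherits(masks, "wt_mask_stack"))
  dt <- frame_interval_s %||% masks$frame_interval_s
  full <- vapply(masks$masks, function(m) sum(m) > 0 && !mask_touches_border(m),
                 logical(1))
  r <- rle(full)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values)
  if (length(ok) == 0L) {
    return(list(eligible = FALSE, longest_run_frames = 0L,
                run_start = NA_integer_, run_end = NA_integer_,
                run_seconds = 0, full_body = full))
  }
  best <- ok[which.max(r$lengths[ok])]
  n <- r$lengths[best]
  list(eligible = n * dt > min_seconds,
       longest_run_frames = n,
       run_start = starts[best], run_end = ends[best],
       run_seconds = n * dt,
       full_body = full)
}
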