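# Synthetic plate-trace images and fluorescence nuclei images with exact
# ground truth.

#' Rasterize a polyline track
#'
#' Each segment is drawn with Bresenham's line algorithm and thickened by a
#' square dilation of radius `floor((stroke_width_px - 1) / 2)` (so stroke
#' width 1 is the bare Bresenham line). Pixels outside the canvas are
#' clipped.
#'
#' @param vertices 2-column matrix of (row, col) vertices (may be empty).
#' @param stroke_width_px stroke width in pixels (>= 1).
#' @param height,width canvas dimensions.
#' @return Logical matrix: `TRUE` on the rasterized track.
#' @export
rasterize_track <- function(vertices, stroke_width_px = 1L, height = 256L, width = 256L) {
  stopifnot(is.matrix(vertices) || length(vertices) == 0L)
  if (stroke_width_px < 1L) stop("`stroke_width_px` must be >= 1", call. = FALSE)
  mask <- matrix(FALSE, height, width)
  if (length(vertices) == 0L || nrow(vertices) < 2L) return(mask)
  rad <- (as.integer(stroke_width_px) - 1L) %/% 2L
  off <- expand.grid(dr = -rad:rad, dc = -rad:rad)
  for (i in seq_len(nrow(vertices) - 1L)) {
    px <- bresenham(vertices[i, 1L], vertices[i, 2L],
                    vertices[i + 1L, 1L], vertices[i + 1L, 2L])
    for (k in seq_len(nrow(off))) {
      r <- px[, 1L] + off$dr[k]; c <- px[, 2L] + off$dc[k]
      ok <- r >= 1L & r <= height & c >= 1L & c <= width
      mask[cbind(r[ok], c[ok])] <- TRUE
    }
  }
  mask
}

#' Generate a synthetic movement-trace image with ground truth
#'
#' A persistent random-walk polyline (direction is a random perturbation of
#' the previous heading) rasterized as a dark trace on a light background —
#' the polarity of a track carved into a bacterial lawn. Steps that would
#' leave the canvas are reflected at the borders. The ground-truth trace
#' area is the exact count of rasterized pixels (the union: self-crossings
#' are counted once).
#'
#' @param n_steps number of walk steps (0 gives a blank image).
#' @param step_len_px step length in pixels.
#' @param stroke_width_px stroke width (see [rasterize_track()]).
#' @param height,width canvas size.
#' @param turn_sd heading change SD per step, radians.
#' @param noise_sd Gaussian pixel noise SD (0 = noiseless).
#' @param seed integer seed (identical seed, identical image).
#' @return A list: `image` (a [track_image()], background 1, trace 0),
#'   `truth` with `true_trace_area`, `vertices` and the track mask.
#' @export
gen_track_image <- function(n_steps = 40L, step_len_px = 12, stroke_width_px = 3L,
                            height = 256L, width = 256L, turn_sd = 0.6,
                            noise_sd = 0, seed = 1L) {
  stopifnot(n_steps >= 0L, step_len_px > 0, stroke_width_px >= 1L)
  with_seed(seed, {
    r <- height / 2; c <- width / 2
    theta <- runif(1, 0, 2 * pi)
    verts <- matrix(c(round(r), round(c)), 1L, 2L)
    if (n_steps >= 1L) for (i in seq_len(n_steps)) {
      theta <- theta + rnorm(1, 0, turn_sd)
      r <- r + step_len_px * sin(theta)
      c <- c + step_len_px * cos(theta)
      # reflect at the plate borders
      margin <- stroke_width_px + 1
      if (r < margin) r <- 2 * margin - r
      if (r > height - margin) r <- 2 * (height - margin) - r
      if (c < margin) c <- 2 * margin - c
      if (c > width - margin) c <- 2 * (width - margin) - c
      verts <- rbind(verts, c(round(r), round(c)))
    }
    mask <- if (n_steps >= 1L)
      rasterize_track(verts, stroke_width_px, height, width)
    else matrix(FALSE, height, width)
    img <- matrix(1, height, width)
    img[mask] <- 0
    if (noise_sd > 0) img <- img + matrix(rnorm(height * width, 0, noise_sd), height, width)
    list(image = track_image(img, "dark_trace_on_light"),
         truth = list(true_trace_area = sum(mask), vertices = verts,
                      trace_mask = mask))
  })
}

#' Fluorescence image container
#'
#' @param image numeric matrix of intensities (finite).
#' @param channel_label free-text channel description.
#' @return An object of class `wt_fluor_image`.
#' @export
fluorescence_image <- function(image, channel_label = "GFP") {
  check_image_matrix(image)
  structure(list(image = image, channel_label = channel_label),
            class = "wt_fluor_image")
}

#' @export
print.wt_fluor_image <- function(x, ...) {
  cat(sprintf("<wt_fluor_image> %d x %d px (%s), intensity [%.4g, %.4g]\n",
              nrow(x$image), ncol(x$image), x$channel_label,
              min(x$image), max(x$image)))
  invisible(x)
}

#' Read a grayscale fluorescence TIFF
#'
#' @inheritParams fluorescence_image
#' @param path TIFF path.
#' @return A [fluorescence_image()].
#' @export
read_fluorescence_image <- function(path, channel_label = "GFP") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  fluorescence_image(img, channel_label)
}

#' Generate a synthetic nuclei image with ground truth
#'
#' Sum of isotropic Gaussian spots (bright on dark, the polarity of nuclear
#' GFP in a muscle bundle) at integer centres placed by dart throwing with a
#' pairwise minimum separation, plus a constant background and optional
#' Gaussian noise. Centres stay at least `3 * blob_sigma_px` from the image
#' border. An infeasible packing is an error naming the constraint.
#'
#' @param n_nuclei number of nuclei (0 gives a background-only image).
#' @param min_separation_px minimum pairwise centre distance.
#' @param blob_sigma_px Gaussian spot SD in pixels.
#' @param height,width canvas size.
#' @param peak_intensity spot amplitude above background.
#' @param background constant background level.
#' @param noise_sd Gaussian pixel noise SD.
#' @param seed integer seed.
#' @param max_attempts dart-throwing attempts before declaring the packing
#'   infeasible.
#' @return A list: `image` (a [fluorescence_image()]) and `truth` with
#'   `true_nuclei_centers` (n x 2 matrix of (row, col)) and `n_nuclei`.
#' @export
gen_nuclei_image <- function(n_nuclei = 16L, min_separation_px = 12,
                             blob_sigma_px = 2, height = 128L, width = 128L,
                             peak_intensity = 1, background = 0.1,
                             noise_sd = 0, seed = 1L, max_attempts = 10000L) {
  stopifnot(n_nuclei >= 0L, min_separation_px > 0, blob_sigma_px > 0)
  margin <- ceiling(3 * blob_sigma_px)
  if (height - 2 * margin < 1 || width - 2 * margin < 1)
    stop("canvas too small for the spot size", call. = FALSE)
  with_seed(seed, {
    centers <- matrix(numeric(), 0L, 2L)
    attempts <- 0L
    while (nrow(centers) < n_nuclei) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop(sprintf(paste0("cannot place %d nuclei at min_separation %g px ",
                            "within a %d x %d canvas (placed %d)"),
                     n_nuclei, min_separation_px, height, width, nrow(centers)),
             call. = FALSE)
      cand <- c(floor(runif(1, margin + 1L, height - margin + 1L)),
                floor(runif(1, margin + 1L, width - margin + 1L)))
      if (nrow(centers) == 0L ||
          all(sqrt((centers[, 1L] - cand[1L])^2 + (centers[, 2L] - cand[2L])^2) >=
              min_separation_px))
        centers <- rbind(centers, cand)
    }
    img <- matrix(background, height, width)
    if (n_nuclei > 0L) {
      rr <- matrix(seq_len(height), height, width)
      cc <- matrix(seq_len(width), height, width, byrow = TRUE)
      for (i in seq_len(n_nuclei)) {
        d2 <- (rr - centers[i, 1L])^2 + (cc - centers[i, 2L])^2
        img <- img + peak_intensity * exp(-d2 / (2 * blob_sigma_px^2))
      }
    }
    if (noise_sd > 0) img <- img + matrix(rnorm(height * width, 0, noise_sd), height, width)
    rownames(centers) <- NULL
    list(image = fluorescence_image(img, "synthetic nuclear GFP"),
         truth = list(true_nuclei_centers = centers, n_nuclei = as.integer(n_nuclei)))
  })
}
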