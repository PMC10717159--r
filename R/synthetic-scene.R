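# Synthetic contraction-assay scenes: area signals and worm movies with
# exact ground truth.

#' Specification of a synthetic single-worm scene
#'
#' Describes a movie (or bare area signal) of one worm whose body area
#' oscillates as the muscle contracts and relaxes:
#' \deqn{area(t) = baseline - (A/2)\,(1 - \cos(2\pi f t)) + noise,}
#' with `t = (frame - 1) * frame_interval_s`. The worm is fully relaxed
#' (maximal area) at the first frame; contraction troughs — the analytic
#' minima of the cosine — are the ground-truth contractions.
#'
#' @param image_height,image_width frame dimensions in pixels (movies only).
#' @param n_frames number of frames (>= 1). The assay default, 143 frames at
#'   0.07 s, is a ten-second recording.
#' @param frame_interval_s seconds per frame (> 0), default 0.07.
#' @param baseline_area relaxed body area in px^2.
#' @param contraction_amplitude peak-to-trough area excursion `A` in px^2.
#'   Must satisfy `baseline_area > contraction_amplitude / 2`.
#' @param contraction_freq_hz contraction frequency `f` in 1/s (>= 0).
#' @param pixel_noise_sd SD of i.i.d. Gaussian pixel noise added to rendered
#'   frames (intensity units; foreground-background contrast is 1).
#' @param area_noise_sd SD of Gaussian noise added directly to the area
#'   signal by [gen_area_series()] (px^2; movies ignore this and acquire
#'   area noise only through pixel noise and segmentation).
#' @param body_touches_border_frames integer frame indices (1-based) at
#'   which the rendered worm is shifted so that it is clipped by the image
#'   edge — used to exercise the full-body QC filter.
#' @param seed integer seed; identical specs (seed included) generate
#'   bit-identical output.
#' @return An object of class `wt_scene_spec`.
#' @export
worm_scene_spec <- function(image_height = 60L, image_width = 80L,
                            n_frames = 143L, frame_interval_s = 0.07,
                            baseline_area = 350, contraction_amplitude = 100,
                            contraction_freq_hz = 1, pixel_noise_sd = 0.1,
                            area_noise_sd = 0, body_touches_border_frames = integer(),
                            seed = 1L) {
  stop_if_not_scalar_number(n_frames, "n_frames", 1)
  stop_if_not_scalar_number(frame_interval_s, "frame_interval_s", 0, strict_min = TRUE)
  stop_if_not_scalar_number(baseline_area, "baseline_area", 0, strict_min = TRUE)
  stop_if_not_scalar_number(contraction_amplitude, "contraction_amplitude", 0)
  stop_if_not_scalar_number(contraction_freq_hz, "contraction_freq_hz", 0)
  stop_if_not_scalar_number(pixel_noise_sd, "pixel_noise_sd", 0)
  stop_if_not_scalar_number(area_noise_sd, "area_noise_sd", 0)
  if (baseline_area <= contraction_amplitude / 2)
    stop("`baseline_area` must exceed `contraction_amplitude`/2 (areas would go negative)",
         call. = FALSE)
  structure(list(image_height = as.integer(image_height),
                 image_width = as.integer(image_width),
                 n_frames = as.integer(n_frames),
                 frame_interval_s = frame_interval_s,
                 baseline_area = baseline_area,
                 contraction_amplitude = contraction_amplitude,
                 contraction_freq_hz = contraction_freq_hz,
                 pixel_noise_sd = pixel_noise_sd,
                 area_noise_sd = area_noise_sd,
                 body_touches_border_frames = as.integer(body_touches_border_frames),
                 seed = seed),
            class = "wt_scene_spec")
}

# Analytic area signal and trough bookkeeping shared by both generators.
scene_truth <- function(spec) {
  t <- (seq_len(spec$n_frames) - 1) * spec$frame_interval_s
  area <- spec$baseline_area -
    (spec$contraction_amplitude / 2) * (1 - cos(2 * pi * spec$contraction_freq_hz * t))
  t_end <- t[length(t)]
  if (spec$contraction_amplitude > 0 && spec$contraction_freq_hz > 0) {
    k <- 0:floor(spec$contraction_freq_hz * t_end + 0.5)  # generous upper bound
    t_trough <- (2 * k + 1) / (2 * spec$contraction_freq_hz)
    t_trough <- t_trough[t_trough <= t_end + 1e-9]
  } else {
    t_trough <- numeric()
  }
  frames <- pmin(pmax(floor(t_trough / spec$frame_interval_s + 0.5) + 1, 1), spec$n_frames)
  list(time_s = t, area = area,
       true_trough_frames = as.integer(frames),
       true_n_contractions = length(frames))
}

#' Generate a synthetic body-area series with ground truth
#'
#' Draws the analytic cosine area signal of a [worm_scene_spec()] plus
#' optional Gaussian area noise (`area_noise_sd`).
#'
#' @param spec a [worm_scene_spec()].
#' @return A list with components `series` (a [area_series()]) and `truth`,
#'   a list with `true_area_per_frame`, `true_trough_frames` (1-based) and
#'   `true_n_contractions`.
#' @export
gen_area_series <- function(spec) {
  stopifnot(inherits(spec, "wt_scene_spec"))
  tr <- scene_truth(spec)
  area <- tr$area
  if (spec$area_noise_sd > 0)
    area <- with_seed(spec$seed, area + rnorm(length(area), 0, spec$area_noise_sd))
  area <- pmax(area, 0)
  list(series = area_series(area, spec$frame_interval_s),
       truth = list(true_area_per_frame = tr$area,
                    true_trough_frames = tr$true_trough_frames,
                    true_n_contractions = tr$true_n_contractions))
}

#' Generate a synthetic single-worm movie with ground truth
#'
#' Renders one bright worm (a thickened sinusoidal tube on a dark
#' background, contrast 1) per frame. The tube thickness is modulated so
#' that the foreground pixel count equals the rounded analytic area signal
#' *exactly* before noise is added: pixels are ranked by distance to a
#' fixed sinusoidal centreline and the closest `area[t]` pixels form the
#' body. Frames listed in `body_touches_border_frames` are shifted so the
#' body is clipped by the top image edge (these frames fail the full-body
#' QC filter by construction).
#'
#' @param spec a [worm_scene_spec()].
#' @return A list with components `stack` (a [frame_stack()]) and `truth`
#'   with `true_area_per_frame` (integer pixel counts), `true_trough_frames`
#'   and `true_n_contractions`.
#' @export
gen_worm_movie <- function(spec) {
  stopifnot(inherits(spec, "wt_scene_spec"))
  H <- spec$image_height; W <- spec$image_width
  tr <- scene_truth(spec)
  areas <- as.integer(round(tr$area))

  with_seed(spec$seed, {
    # fixed sinusoidal centreline spanning 70% of the width
    c0 <- 0.15 * W; c1 <- 0.85 * W
    phase <- runif(1, 0, 2 * pi)
    cs <- seq(c0, c1, length.out = 4L * ceiling(c1 - c0))
    rs <- H / 2 + 0.18 * H * sin(2 * pi * 1.5 * (cs - c0) / (c1 - c0) + phase)

    px_r <- rep(seq_len(H), times = W)
    px_c <- rep(seq_len(W), each = H)
    d2 <- rep(Inf, H * W)
    for (j in seq_along(cs))
      d2 <- pmin(d2, (px_r - rs[j])^2 + (px_c - cs[j])^2)
    ord <- order(d2, seq_along(d2))

    a_max <- max(areas)
    if (a_max > length(ord))
      stop("worm region cannot fit in the image dimensions", call. = FALSE)
    sel_max <- ord[seq_len(a_max)]
    if (any(px_r[sel_max] %in% c(1L, H)) || any(px_c[sel_max] %in% c(1L, W)))
      stop("worm region cannot fit in the image dimensions without touching the border",
           call. = FALSE)

    frames <- vector("list", spec$n_frames)
    for (t in seq_len(spec$n_frames)) {
      sel <- ord[seq_len(areas[t])]
      if (t %in% spec$body_touches_border_frames) {
        # shift the body so it is clipped by the top edge
        shift <- min(px_r[sel])
        r <- px_r[sel] - shift; c <- px_c[sel]
        keep <- r >= 1L
        idx <- r[keep] + (c[keep] - 1L) * H
      } else {
        idx <- sel
      }
      f <- matrix(0, H, W)
      f[idx] <- 1
      if (spec$pixel_noise_sd > 0)
        f <- f + matrix(rnorm(H * W, 0, spec$pixel_noise_sd), H, W)
      frames[[t]] <- f
    }
    list(stack = frame_stack(frames, spec$frame_interval_s),
         truth = list(true_area_per_frame = areas,
                      true_trough_frames = tr$true_trough_frames,
                      true_n_contractions = tr$true_n_contractions))
  })
}
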