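# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards. Generators are pure
# functions of their spec (seed included) because of this.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stop_if_not_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (strict_min && x <= min)
    stop(sprintf("`%s` must be > %g", name, min), call. = FALSE)
  if (!strict_min && x < min)
    stop(sprintf("`%s` must be >= %g", name, min), call. = FALSE)
  invisible(x)
}

check_image_matrix <- function(img, name = "image") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  if (any(!is.finite(img)))
    stop(sprintf("`%s` contains non-finite pixel values", name), call. = FALSE)
  invisible(img)
}

# Histogram Otsu threshold (256 levels over the observed range).
# Returns a threshold on the intensity scale of `x`; pixels strictly above
# it are foreground. For a constant image there is no foreground and NA is
# returned.
otsu_threshold <- function(x, levels = 256L) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(NA_real_)
  bin <- pmin(as.integer((x - rng[1]) / (rng[2] - rng[1]) * levels) + 1L, levels)
  h <- tabulate(bin, nbins = levels)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(levels) - 0.5) * (rng[2] - rng[1]) / levels
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[levels]
  # between-class variance for threshold after bin t (t = 1..levels-1)
  w0 <- w0[-levels]; mu <- mu[-levels]
  valid <- w0 > 0 & w0 < 1
  bcv <- rep(-Inf, levels - 1L)
  bcv[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * (1 - w0[valid]))
  t_star <- which.max(bcv)
  # threshold at the upper edge of bin t_star
  rng[1] + t_star * (rng[2] - rng[1]) / levels
}

# 8-connected component labelling (Rcpp backend).
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  .label8(matrix(as.logical(mask), nrow(mask), ncol(mask)))
}

# Keep only the largest 8-connected foreground component with size >=
# min_px; returns a logical matrix (possibly empty).
largest_component <- function(mask, min_px = 0L) {
  lab <- label_components(mask)
  n <- max(lab)
  if (n == 0L) return(matrix(FALSE, nrow(mask), ncol(mask)))
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  best <- which.max(sizes)
  if (sizes[best] < min_px) return(matrix(FALSE, nrow(mask), ncol(mask)))
  lab == best
}

# Drop all components smaller than min_px (speck removal; keeps every
# sufficiently large component, unlike largest_component()).
remove_small_components <- function(mask, min_px) {
  lab <- label_components(mask)
  n <- max(lab)
  if (n == 0L) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  keep <- which(sizes >= min_px)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

mask_touches_border <- function(mask) {
  any(mask[1, ]) || any(mask[nrow(mask), ]) ||
    any(mask[, 1]) || any(mask[, ncol(mask)])
}

# Centered moving average with edge truncation (window must be odd).
# Computed as direct window means, not via cumulative sums: plateau-aware
# peak detection compares smoothed values for exact equality, so the
# arithmetic must be free of cancellation artifacts.
moving_average <- function(x, window) {
  stopifnot(window >= 1L, window %% 2L == 1L)
  if (window == 1L) return(x)
  n <- length(x)
  if (window > n) stop("smoothing window longer than the series", call. = FALSE)
  half <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i)
    mean(x[max(1L, i - half):min(n, i + half)]), numeric(1))
}

# Integer Bresenham line rasterization; returns a 2-column matrix (row, col).
bresenham <- function(r0, c0, r1, c1) {
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- if (r0 < r1) 1L else -1L
  sc <- if (c0 < c1) 1L else -1L
  err <- dr - dc
  n <- max(dr, dc) + 1L
  out <- matrix(0L, n, 2L)
  r <- r0; c <- c0
  for (i in seq_len(n)) {
    out[i, ] <- c(r, c)
    if (r == r1 && c == c1) break
    e2 <- 2L * err
    if (e2 > -dc) { err <- err - dc; r <- r + sr }
    if (e2 < dr)  { err <- err + dr; c <- c + sc }
  }
  out[seq_len(i), , drop = FALSE]
}

# Most frequent value of a numeric vector. Exact tabulation when the number
# of distinct values is modest (noiseless synthetic images, integer data);
# otherwise the midpoint of the fullest 256-bin histogram cell.
intensity_mode <- function(x, max_unique = 1024L) {
  ux <- unique(x)
  if (length(ux) <= max_unique) {
    ux[which.max(tabulate(match(x, ux)))]
  } else {
    h <- graphics::hist(x, breaks = 256L, plot = FALSE)
    h$mids[which.max(h$counts)]
  }
}
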