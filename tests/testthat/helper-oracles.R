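# Independent oracle implementations used to check the package against.
# The peak and studentized-range oracles are shared with the validation
# scripts and live under inst/validation/ (single source of truth).

source(system.file("validation", "peak-oracle.R", package = "wormtwitch"),
       local = environment())
source(system.file("validation", "srange-oracle.R", package = "wormtwitch"),
       local = environment())

# --- flood-fill 8-connected labelling ---------------------------------------
oracle_label8 <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  comp <- 0L
  for (c0 in seq_len(W)) for (r0 in seq_len(H)) {
    if (!mask[r0, c0] || lab[r0, c0] > 0L) next
    comp <- comp + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- comp
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1L] + dr; c <- p[2L] + dc
        if (r < 1L || r > H || c < 1L || c > W) next
        if (mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- comp
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# --- random series generator for detector-vs-oracle comparisons -------------
# Mixture of smooth oscillations, random walks (integer-valued walks create
# plateaus) and white noise.
random_test_series <- function(n, kind = c("smooth", "walk", "noise")) {
  kind <- match.arg(kind)
  switch(kind,
    smooth = 5 * sin(2 * pi * runif(1, 0.5, 3) * seq_len(n) / n * 3 + runif(1, 0, 6)) +
      rnorm(n, 0, runif(1, 0, 1.5)),
    walk = cumsum(sample(c(-1L, 0L, 1L), n, replace = TRUE)),
    noise = rnorm(n))
}
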