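# Brute-force reference implementation of the peak-detection contract:
# centred moving average, plateau-aware local extrema with endpoints
# excluded, topographic prominence via explicit walks, and the documented
# tie rules for upper peaks. Deliberately naive; shares no code with the
# package internals.
oracle_peaks <- function(x, window = 1L, prominence = 0) {
  n <- length(x)
  half <- (window - 1L) %/% 2L
  s <- numeric(n)
  for (i in seq_len(n)) s[i] <- mean(x[max(1L, i - half):min(n, i + half)])

  run_id <- integer(n)
  run_id[1L] <- 1L
  if (n > 1L) for (i in 2:n) run_id[i] <- run_id[i - 1L] + (s[i] != s[i - 1L])
  nr <- run_id[n]
  vals <- reps <- numeric(nr)
  for (j in seq_len(nr)) {
    idx <- which(run_id == j)
    vals[j] <- s[idx[1L]]
    reps[j] <- idx[1L] + (length(idx) - 1L) %/% 2L
  }
  is_min <- is_max <- logical(nr)
  for (j in seq_len(nr)) {
    if (j == 1L || j == nr) next
    is_min[j] <- vals[j - 1L] > vals[j] && vals[j + 1L] > vals[j]
    is_max[j] <- vals[j - 1L] < vals[j] && vals[j + 1L] < vals[j]
  }
  prom_of <- function(j) {
    v <- vals[j]
    walk <- function(dir) {
      jj <- j + dir
      best <- -Inf
      while (jj >= 1L && jj <= nr && vals[jj] >= v) {
        best <- max(best, vals[jj])
        jj <- jj + dir
      }
      best - v
    }
    min(walk(-1L), walk(1L))
  }
  lows <- integer()
  for (j in which(is_min)) if (prom_of(j) >= prominence) lows <- c(lows, reps[j])

  uppers <- integer()
  if (length(lows) >= 2L) for (k in seq_len(length(lows) - 1L)) {
    win <- (lows[k] + 1L):(lows[k + 1L] - 1L)
    m <- -Inf
    for (i in win) m <- max(m, s[i])
    ties <- win[sapply(win, function(i) s[i] == m)]
    uppers <- c(uppers, ties[(length(ties) + 1L) %/% 2L])
  }
  if (length(lows) >= 1L) {
    lead <- which(is_max)[reps[which(is_max)] < lows[1L]]
    if (length(lead)) {
      best <- max(vals[lead])
      uppers <- c(uppers, reps[max(lead[vals[lead] == best])])
    }
    trail <- which(is_max)[reps[which(is_max)] > lows[length(lows)]]
    if (length(trail)) {
      best <- max(vals[trail])
      uppers <- c(uppers, reps[min(trail[vals[trail] == best])])
    }
  }
  list(lower = as.integer(lows), upper = as.integer(sort(uppers)))
}
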