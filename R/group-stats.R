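# Group-comparison statistics: mean +/- SEM summaries, one-way fixed-effects
# ANOVA, and Tukey HSD (Tukey-Kramer for unequal group sizes).

# Resolve a `value ~ condition` formula against a data frame into a numeric
# response and a grouping factor.
resolve_groups <- function(formula, data) {
  stopifnot(inherits(formula, "formula"))
  mf <- stats::model.frame(formula, data)
  if (ncol(mf) != 2L)
    stop("formula must have the form `value ~ condition`", call. = FALSE)
  y <- mf[[1L]]
  g <- factor(mf[[2L]])
  if (!is.numeric(y) || any(!is.finite(y)))
    stop("response values must be finite numbers", call. = FALSE)
  g <- droplevels(g)
  list(y = y, g = g)
}

#' Per-condition mean, SEM and n
#'
#' The standard error of the mean is the sample SD (n - 1 denominator)
#' divided by sqrt(n). Groups of size 1 get SEM 0 and a warning flag.
#'
#' @param formula `value ~ condition`.
#' @param data a data frame of per-animal measurements.
#' @return A data frame with columns `condition`, `n`, `mean`, `sem`,
#'   `sem_undefined` (TRUE for n = 1).
#' @export
summarize_groups <- function(formula, data) {
  gr <- resolve_groups(formula, data)
  if (length(gr$y) == 0L) stop("empty table", call. = FALSE)
  conds <- levels(gr$g)
  out <- do.call(rbind, lapply(conds, function(cc) {
    v <- gr$y[gr$g == cc]
    n <- length(v)
    data.frame(condition = cc, n = n, mean = mean(v),
               sem = if (n > 1L) sd(v) / sqrt(n) else 0,
               sem_undefined = n == 1L)
  }))
  if (any(out$sem_undefined))
    warning("SEM reported as 0 for single-animal condition(s)", call. = FALSE)
  rownames(out) <- NULL
  out
}

#' One-way fixed-effects ANOVA
#'
#' Standard decomposition: `F = MS_between / MS_within` with
#' `df = (k - 1, N - k)` and the p value from the upper tail of the F
#' distribution. Zero between-group variance gives F = 0, p = 1; zero
#' within-group variance with nonzero between gives F = +Inf, p = 0. A
#' Brown-Forsythe (median-centred Levene) heterogeneity check is computed
#' as an advisory: a warning is emitted when its p < 0.01, but the ANOVA is
#' reported unconditionally.
#'
#' @inheritParams summarize_groups
#' @return An object of class `wt_anova`: `F`, `df_between`, `df_within`,
#'   `p_value`, sums of squares, a `groups` summary (as
#'   [summarize_groups()]), the `homogeneity` advisory, and the model frame
#'   for [tukey_hsd()].
#' @export
one_way_anova <- function(formula, data) {
  gr <- resolve_groups(formula, data)
  k <- nlevels(gr$g)
  if (k < 2L) stop("need at least 2 conditions", call. = FALSE)
  ns <- tabulate(gr$g)
  if (any(ns < 2L)) stop("need at least 2 values per condition", call. = FALSE)
  N <- length(gr$y)
  means <- tapply(gr$y, gr$g, mean)
  grand <- mean(gr$y)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((gr$y - means[gr$g])^2)
  df1 <- k - 1L; df2 <- N - k
  if (ssb <= 0) { f <- 0; p <- 1 }
  else if (ssw <= 0) { f <- Inf; p <- 0 }
  else { f <- (ssb / df1) / (ssw / df2); p <- pf(f, df1, df2, lower.tail = FALSE) }

  # Brown-Forsythe advisory on variance homogeneity
  z <- abs(gr$y - tapply(gr$y, gr$g, median)[gr$g])
  zm <- tapply(z, gr$g, mean)
  bf_ssb <- sum(ns * (zm - mean(z))^2)
  bf_ssw <- sum((z - zm[gr$g])^2)
  bf <- if (bf_ssb > 0 && bf_ssw > 0) {
    bf_f <- (bf_ssb / df1) / (bf_ssw / df2)
    list(F = bf_f, p_value = pf(bf_f, df1, df2, lower.tail = FALSE))
  } else list(F = 0, p_value = 1)
  if (bf$p_value < 0.01)
    warning("group variances look heterogeneous (Brown-Forsythe p < 0.01); ANOVA reported anyway",
            call. = FALSE)

  sems <- vapply(split(gr$y, gr$g), function(v) sd(v) / sqrt(length(v)), numeric(1))
  groups <- data.frame(condition = levels(gr$g), n = ns,
                       mean = as.numeric(means), sem = unname(sems),
                       sem_undefined = FALSE)
  structure(list(F = f, df_between = df1, df_within = df2, p_value = p,
                 ss_between = ssb, ss_within = ssw,
                 ms_within = if (df2 > 0) ssw / df2 else NA_real_,
                 groups = groups,
                 homogeneity = bf,
                 .y = gr$y, .g = gr$g, call = match.call()),
            class = "wt_anova")
}

#' @export
print.wt_anova <- function(x, ...) {
  cat("One-way ANOVA\n")
  cat(sprintf("  F(%d, %d) = %s, p = %s\n", x$df_between, x$df_within,
              format(x$F, digits = 5), format.pval(x$p_value, digits = 4)))
  cat(sprintf("  SS between = %.6g, SS within = %.6g\n", x$ss_between, x$ss_within))
  cat("  Group means +/- SEM:\n")
  g <- x$groups
  for (i in seq_len(nrow(g)))
    cat(sprintf("    %-24s %s +/- %s (n = %d)\n", g$condition[i],
                format(g$mean[i], digits = 4), format(g$sem[i], digits = 3), g$n[i]))
  if (x$homogeneity$p_value < 0.01)
    cat("  note: Brown-Forsythe heterogeneity p < 0.01 (advisory)\n")
  invisible(x)
}

#' @export
coef.wt_anova <- function(object, ...) {
  stats::setNames(object$groups$mean, object$groups$condition)
}

#' Tukey honestly-significant-difference test
#'
#' All-pairs comparison after a one-way ANOVA. For each pair,
#' `q = |mean_A - mean_B| / sqrt(MS_within * (1/n_A + 1/n_B) / 2)` (the
#' Tukey-Kramer form, exact for equal n) and the adjusted p value is the
#' upper tail of the studentized range distribution with `k` groups and the
#' ANOVA's within-group degrees of freedom. Pairs are flagged significant
#' at `alpha`.
#'
#' @param x a `wt_anova` fit, or a `value ~ condition` formula.
#' @param data data frame (when `x` is a formula).
#' @param alpha family-wise significance level (default 0.05).
#' @return An object of class `wt_tukey`: a data frame with one row per
#'   unordered pair (`condition_a`, `condition_b`, `mean_diff`, `q`,
#'   `p_adj`, `significant`), with the ANOVA attached as an attribute.
#' @export
tukey_hsd <- function(x, data = NULL, alpha = 0.05) {
  fit <- if (inherits(x, "wt_anova")) x else one_way_anova(x, data)
  k <- fit$df_between + 1L
  means <- tapply(fit$.y, fit$.g, mean)
  ns <- tabulate(fit$.g)
  conds <- levels(fit$.g)
  pairs <- combn(k, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    diff <- means[b] - means[a]
    se <- sqrt(fit$ms_within * (1 / ns[a] + 1 / ns[b]) / 2)
    q <- if (se > 0) abs(diff) / se else if (diff == 0) 0 else Inf
    p <- if (is.infinite(q)) 0 else if (q == 0) 1
         else ptukey(q, nmeans = k, df = fit$df_within, lower.tail = FALSE)
    data.frame(condition_a = conds[a], condition_b = conds[b],
               mean_diff = unname(diff), q = unname(q), p_adj = unname(p),
               significant = unname(p < alpha))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("wt_tukey", "data.frame"),
            anova = fit, alpha = alpha)
}

#' @export
print.wt_tukey <- function(x, ...) {
  fit <- attr(x, "anova")
  cat(sprintf("Tukey HSD (k = %d, df = %d, alpha = %g)\n",
              fit$df_between + 1L, fit$df_within, attr(x, "alpha")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
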