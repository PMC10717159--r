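# Mean ± SEM summaries, one-way ANOVA and Tukey HSD.

three_groups <- function() data.frame(
  value = c(1, 2, 3, 2, 3, 4, 3, 4, 5),
  condition = rep(c("g1", "g2", "g3"), each = 3))

test_that("group summaries report mean, SEM and n", {
  s <- summarize_groups(value ~ condition, three_groups())
  expect_equal(s$mean, c(2, 3, 4))
  expect_equal(s$sem, rep(1 / sqrt(3), 3))
  expect_identical(s$n, rep(3L, 3))

  # single animal: SEM 0 plus a warning flag
  d1 <- data.frame(value = c(5, 1, 2), condition = c("a", "b", "b"))
  expect_warning(s1 <- summarize_groups(value ~ condition, d1), "single-animal")
  expect_equal(s1$sem[s1$condition == "a"], 0)
  expect_true(s1$sem_undefined[s1$condition == "a"])

  # constant group: SEM 0 without flags
  dc <- data.frame(value = rep(7, 4), condition = "a")
  sc <- summarize_groups(value ~ condition, dc)
  expect_equal(sc$sem, 0)
  expect_false(sc$sem_undefined)

  expect_error(summarize_groups(value ~ condition,
                                data.frame(value = numeric(), condition = character())),
               "empty")
})

test_that("one-way ANOVA reproduces the hand-computed decomposition", {
  fit <- one_way_anova(value ~ condition, three_groups())
  expect_equal(fit$ss_between, 6)
  expect_equal(fit$ss_within, 6)
  expect_identical(c(fit$df_between, fit$df_within), c(2L, 6L))
  expect_equal(fit$F, 3)
  # cross-check against the base linear-model route
  ref <- anova(lm(value ~ condition, three_groups()))
  expect_equal(fit$F, ref$`F value`[1])
  expect_equal(fit$p_value, ref$`Pr(>F)`[1])

  # identical groups: F = 0, p = 1
  same <- data.frame(value = rep(c(1, 2, 3), 3),
                     condition = rep(c("a", "b", "c"), each = 3))
  fit0 <- one_way_anova(value ~ condition, same)
  expect_identical(fit0$F, 0)
  expect_identical(fit0$p_value, 1)

  # zero within-group variance with nonzero between: F = +Inf, p = 0
  det <- data.frame(value = rep(c(1, 2), each = 3),
                    condition = rep(c("a", "b"), each = 3))
  fitI <- suppressWarnings(one_way_anova(value ~ condition, det))
  expect_identical(fitI$F, Inf)
  expect_identical(fitI$p_value, 0)

  expect_error(one_way_anova(value ~ condition,
                             data.frame(value = 1:3, condition = "a")),
               "at least 2 conditions")
  expect_error(one_way_anova(value ~ condition,
                             data.frame(value = 1:3, condition = c("a", "b", "b"))),
               "at least 2 values")
})

test_that("two-group ANOVA equals the squared pooled-variance t statistic", {
  set.seed(31)
  for (i in 1:10) {
    d <- data.frame(value = c(rnorm(8, 0), rnorm(11, 0.8)),
                    condition = rep(c("a", "b"), c(8, 11)))
    fit <- suppressWarnings(one_way_anova(value ~ condition, d))
    tt <- t.test(value ~ condition, d, var.equal = TRUE)
    expect_equal(fit$F, unname(tt$statistic)^2)
    expect_equal(fit$p_value, tt$p.value)
  }
})

test_that("the ANOVA decomposition is exact on random tables", {
  set.seed(17)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    ns <- sample(2:12, k, replace = TRUE)
    d <- data.frame(value = rnorm(sum(ns), rep(rnorm(k, 0, 2), ns), 1),
                    condition = rep(letters[1:k], ns))
    fit <- suppressWarnings(one_way_anova(value ~ condition, d))
    sst <- sum((d$value - mean(d$value))^2)
    expect_lt(abs(fit$ss_between + fit$ss_within - sst) / sst, 1e-9)
  }
})

test_that("Tukey HSD reproduces the hand-computed q and the base-R reference", {
  h <- tukey_hsd(value ~ condition, three_groups())
  expect_identical(nrow(h), 3L)   # all k(k-1)/2 pairs
  ext <- h[h$condition_a == "g1" & h$condition_b == "g3", ]
  expect_equal(ext$mean_diff, 2)
  expect_equal(ext$q, 2 * sqrt(3))
  expect_true(all((h$p_adj < 0.05) == h$significant))

  # identical pair of groups: q = 0, adjusted p = 1
  dup <- data.frame(value = c(1, 2, 3, 1, 2, 3), condition = rep(c("a", "b"), each = 3))
  h0 <- tukey_hsd(value ~ condition, dup)
  expect_identical(h0$q, 0)
  expect_identical(h0$p_adj, 1)

  # unequal group sizes against TukeyHSD (Tukey-Kramer in both)
  set.seed(23)
  d <- data.frame(value = rnorm(24, rep(c(0, 1, 3), c(6, 8, 10))),
                  condition = rep(c("a", "b", "c"), c(6, 8, 10)))
  mine <- tukey_hsd(value ~ condition, d)
  ref <- TukeyHSD(aov(value ~ condition, d))$condition
  expect_equal(mine$p_adj, unname(ref[, "p adj"]), tolerance = 1e-8)
  expect_equal(abs(mine$mean_diff), unname(abs(ref[, "diff"])), tolerance = 1e-10)
})

test_that("adjusted p values match the quadrature oracle and decrease in q", {
  for (k in c(3L, 5L)) for (df in c(6L, 30L)) {
    qs <- c(0.8, 2.5, 4.0)
    ps <- vapply(qs, function(q) ptukey(q, k, df, lower.tail = FALSE), numeric(1))
    oracle <- vapply(qs, function(q) oracle_srange_upper(q, k, df), numeric(1))
    expect_equal(ps, oracle, tolerance = 1e-6)
    expect_true(all(diff(ps) < 0))   # strictly decreasing in q
  }
})

test_that("label permutations leave F marginally F-distributed", {
  set.seed(1)
  d <- data.frame(value = rnorm(30), condition = rep(c("a", "b", "c"), each = 10))
  # relabeling animals within a condition changes nothing
  fit <- one_way_anova(value ~ condition, d)
  d2 <- d[c(10:1, 11:30), ]
  expect_equal(one_way_anova(value ~ condition, d2)$F, fit$F)
  # full label permutation: simulated null of F matches the F(2, 27) law
  fs <- replicate(10000, {
    dd <- d; dd$condition <- sample(dd$condition)
    suppressWarnings(one_way_anova(value ~ condition, dd))$F
  })
  ks <- suppressWarnings(ks.test(fs, pf, df1 = 2, df2 = 27))
  expect_gt(ks$p.value, 0.01)
})
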