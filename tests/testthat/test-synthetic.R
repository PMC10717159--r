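# Generators: determinism, ground-truth bookkeeping, error contracts.

test_that("area-series generator matches the closed-form cosine and its troughs", {
  # zero amplitude: constant series, no contractions
  g0 <- gen_area_series(worm_scene_spec(baseline_area = 1000, contraction_amplitude = 0,
                                        area_noise_sd = 0, n_frames = 50))
  expect_equal(g0$series$area_px2, rep(1000, 50))
  expect_identical(g0$truth$true_n_contractions, 0L)
  expect_length(g0$truth$true_trough_frames, 0)

  # 1 Hz over 43 frames at 0.07 s: analytic troughs at t = 0.5, 1.5, 2.5 s
  g <- gen_area_series(worm_scene_spec(baseline_area = 1000, contraction_amplitude = 200,
                                       contraction_freq_hz = 1, n_frames = 43,
                                       frame_interval_s = 0.07, area_noise_sd = 0))
  expect_identical(g$truth$true_n_contractions, 3L)
  # trough frames are the samples nearest 0.5/1.5/2.5 s (1-based)
  expect_identical(g$truth$true_trough_frames, c(8L, 22L, 37L))
  expect_equal(min(g$series$area_px2), 1000 - 200, tolerance = 1e-3)
  expect_equal(g$series$area_px2[1], 1000)
})

test_that("generators are pure functions of their spec, seed included", {
  sp <- worm_scene_spec(n_frames = 20, area_noise_sd = 3, pixel_noise_sd = 0.1, seed = 7)
  expect_identical(gen_area_series(sp), gen_area_series(sp))
  expect_identical(gen_worm_movie(sp), gen_worm_movie(sp))
  expect_identical(gen_track_image(seed = 7, noise_sd = 0.05),
                   gen_track_image(seed = 7, noise_sd = 0.05))
  expect_identical(gen_nuclei_image(seed = 7, noise_sd = 0.02),
                   gen_nuclei_image(seed = 7, noise_sd = 0.02))
  spc <- cohort_preset("contractility", seed = 7)
  expect_identical(gen_cohort(spc), gen_cohort(spc))
  # generators restore the caller's RNG state
  set.seed(123); before <- .Random.seed
  invisible(gen_worm_movie(sp))
  expect_identical(.Random.seed, before)
})

test_that("scene spec rejects invalid parameters", {
  expect_error(worm_scene_spec(frame_interval_s = 0), "frame_interval_s")
  expect_error(worm_scene_spec(frame_interval_s = -1), "frame_interval_s")
  expect_error(worm_scene_spec(baseline_area = 100, contraction_amplitude = 300),
               "negative")
  expect_error(worm_scene_spec(contraction_freq_hz = -1), "contraction_freq_hz")
})

test_that("rendered movies carry exact foreground counts and border contacts", {
  sp <- worm_scene_spec(n_frames = 12, pixel_noise_sd = 0, contraction_amplitude = 80,
                        baseline_area = 300, body_touches_border_frames = 5L, seed = 2)
  mv <- gen_worm_movie(sp)
  # noiseless frames are exactly {0,1}: foreground count is the pixel sum
  counts <- vapply(mv$stack$frames, sum, numeric(1))
  expect_equal(counts[-5], mv$truth$true_area_per_frame[-5])
  # the border-contact frame is clipped (fewer pixels) and touches the edge
  expect_lt(counts[5], mv$truth$true_area_per_frame[5])
  expect_true(any(mv$stack$frames[[5]][1, ] > 0))
  # non-contact frames stay clear of every border
  f <- mv$stack$frames[[1]]
  expect_false(any(f[1, ] > 0) || any(f[nrow(f), ] > 0) ||
                 any(f[, 1] > 0) || any(f[, ncol(f)] > 0))
})

test_that("a worm too large for the canvas is an error", {
  expect_error(gen_worm_movie(worm_scene_spec(image_height = 12, image_width = 16,
                                              baseline_area = 350, n_frames = 3)),
               "cannot fit")
})

test_that("ground-truth contraction count always equals the trough list length", {
  for (seed in 1:20) {
    set.seed(seed)
    sp <- worm_scene_spec(n_frames = sample(10:200, 1),
                          contraction_freq_hz = runif(1, 0, 3),
                          contraction_amplitude = runif(1, 0, 150),
                          baseline_area = 400, seed = seed)
    g <- gen_area_series(sp)
    expect_identical(g$truth$true_n_contractions, length(g$truth$true_trough_frames))
    expect_true(all(diff(g$truth$true_trough_frames) > 0))
  }
})

test_that("track generator counts the union of rasterized pixels once", {
  # blank path
  blank <- gen_track_image(n_steps = 0, seed = 1)
  expect_identical(blank$truth$true_trace_area, 0L)
  expect_true(all(blank$image$image == 1))

  # a self-crossing figure: union strictly below the sum of segment areas
  verts <- rbind(c(50, 20), c(50, 120), c(20, 70), c(90, 70))
  union_mask <- rasterize_track(verts, 1, 128, 128)
  seg_sum <- 0
  for (i in 1:(nrow(verts) - 1))
    seg_sum <- seg_sum + sum(rasterize_track(verts[i:(i + 1), ], 1, 128, 128))
  expect_lt(sum(union_mask), seg_sum)

  # generated walks agree with their own mask
  g <- gen_track_image(n_steps = 30, seed = 11)
  expect_identical(g$truth$true_trace_area, sum(g$truth$trace_mask))
  expect_identical(sum(g$image$image == 0), sum(g$truth$trace_mask))
})

test_that("nuclei generator respects separation and errors on infeasible packings", {
  g <- gen_nuclei_image(n_nuclei = 16, min_separation_px = 12, noise_sd = 0, seed = 3)
  ctr <- g$truth$true_nuclei_centers
  expect_identical(nrow(ctr), 16L)
  d <- as.matrix(dist(ctr))
  expect_true(all(d[upper.tri(d)] >= 12))

  g0 <- gen_nuclei_image(n_nuclei = 0, seed = 1)
  expect_identical(g0$truth$n_nuclei, 0L)
  expect_identical(nrow(g0$truth$true_nuclei_centers), 0L)

  expect_error(gen_nuclei_image(n_nuclei = 200, min_separation_px = 40,
                                height = 64, width = 64, max_attempts = 2000),
               "cannot place")
})

test_that("cohort generator applies truncation, rounding and the effect model", {
  spec <- cohort_spec(
    data.frame(condition = c("a", "b"), genotype = "g", fbx_dose_ug_ml = 0,
               ua_dose_mM = 0, day = 4),
    endpoints = list(count = list(mean = c(3, 3), sd = 4, nonneg = TRUE, integer = TRUE)),
    n_animals_per_condition = 200, seed = 5)
  tab <- gen_cohort(spec)$table
  expect_true(all(tab$value >= 0))
  expect_true(all(tab$value == round(tab$value)))
  expect_identical(nrow(tab), 400L)

  # degenerate case: identical means, zero SD -> downstream F is exactly 0
  null0 <- cohort_spec(
    data.frame(condition = c("a", "b", "c"), genotype = "g", fbx_dose_ug_ml = 0,
               ua_dose_mM = 0, day = 4),
    endpoints = list(amp = list(mean = 2, sd = 0)), n_animals_per_condition = 10,
    seed = 1)
  t0 <- gen_cohort(null0)$table
  fit <- suppressWarnings(one_way_anova(value ~ condition, t0))
  expect_identical(fit$F, 0)
  expect_identical(fit$p_value, 1)
})
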