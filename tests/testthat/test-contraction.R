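# Deviation series, peak detection and contraction metrics.

worked_series <- function() area_series(c(10, 8, 10, 8, 10), 0.07)

test_that("deviation series implements area minus mean area", {
  dev <- deviation_series(worked_series())
  expect_equal(dev$mean_area_px2, 9.2)
  expect_equal(dev$deviation_px2, c(0.8, -1.2, 0.8, -1.2, 0.8))

  const <- deviation_series(area_series(rep(5, 10), 0.07))
  expect_equal(const$deviation_px2, rep(0, 10))

  set.seed(1)
  for (i in 1:10) {
    dev <- deviation_series(area_series(runif(50, 10, 100), 0.07))
    expect_lt(abs(sum(dev$deviation_px2)) / dev$mean_area_px2, 1e-9)
  }
})

test_that("peak detection resolves the worked series and basic shapes", {
  dev <- deviation_series(worked_series())
  pk <- detect_peaks(dev, smooth_window_frames = 1, min_prominence_px2 = 0.5)
  expect_identical(pk$lower_peak_frames, c(2L, 4L))   # 1-based
  expect_identical(pk$upper_peak_frames, 3L)
  expect_equal(pk$lower_peak_values, c(-1.2, -1.2))
  expect_equal(pk$upper_peak_values, 0.8)

  # monotone series: endpoints are never peaks
  mono <- deviation_series(area_series(seq(100, 50, length.out = 20), 0.07))
  pk2 <- detect_peaks(mono, 1, 0)
  expect_length(pk2$lower_peak_frames, 0)
  expect_length(pk2$upper_peak_frames, 0)

  # clean cosine: detected troughs equal analytic trough frames
  g <- gen_area_series(worm_scene_spec(n_frames = 143, contraction_amplitude = 100,
                                       baseline_area = 400, contraction_freq_hz = 1,
                                       area_noise_sd = 0))
  pk3 <- detect_peaks(deviation_series(g$series), 1, 5)
  expect_identical(pk3$lower_peak_frames, g$truth$true_trough_frames)

  expect_error(detect_peaks(dev, smooth_window_frames = 2), "odd")
  expect_error(detect_peaks(dev, smooth_window_frames = 7), "longer than the series")
})

test_that("upper and lower peaks alternate when merged", {
  set.seed(3)
  for (i in 1:30) {
    x <- random_test_series(120, sample(c("smooth", "walk", "noise"), 1))
    dev <- deviation_series(area_series(x - min(x), 0.07))
    pk <- detect_peaks(dev, 3, 0.2)
    merged <- rbind(data.frame(i = pk$lower_peak_frames, kind = "L"),
                    data.frame(i = pk$upper_peak_frames, kind = "U"))
    merged <- merged[order(merged$i), ]
    if (nrow(merged) > 1)
      expect_true(all(merged$kind[-1] != merged$kind[-nrow(merged)]))
    expect_true(all(diff(pk$lower_peak_frames) > 0))
  }
})

test_that("contraction metrics reproduce the worked formulas", {
  dev <- deviation_series(worked_series())
  pk <- detect_peaks(dev, 1, 0.5)
  m <- contraction_metrics(dev, pk)
  expect_identical(m$n_contractions, 2L)
  expect_equal(m$amplitudes_px2, c(2, 2))   # leading trough uses the start value 0.8
  expect_equal(m$rate_of_change_px2, 2)
  expect_equal(m$frequency_hz, 2 / (5 * 0.07))
  # frequency identity holds exactly
  expect_identical(m$frequency_hz * m$n_analysis_frames * dev$frame_interval_s,
                   as.numeric(m$n_contractions))
  # alternative formula reading divides once more by n
  m2 <- contraction_metrics(dev, pk, amplitude_mode = "excursion_over_n")
  expect_equal(m2$rate_of_change_px2, m$rate_of_change_px2 / m$n_contractions)
})

test_that("a flat series yields zero contractions without error", {
  dev <- deviation_series(area_series(rep(100, 40), 0.07))
  m <- contraction_metrics(dev, detect_peaks(dev, 3, NULL))
  expect_identical(m$n_contractions, 0L)
  expect_identical(m$frequency_hz, 0)
  expect_true(m$rate_undefined)
})

test_that("ten seconds of a 1 Hz cosine gives the closed-form frequency", {
  g <- gen_area_series(worm_scene_spec(n_frames = 142, contraction_amplitude = 100,
                                       baseline_area = 400, contraction_freq_hz = 1,
                                       area_noise_sd = 0))
  expect_identical(g$truth$true_n_contractions, 10L)
  m <- analyze_area_series(g$series, smooth_window_frames = 1, min_prominence_px2 = 5)
  expect_identical(m$n_contractions, 10L)
  expect_equal(m$frequency_hz, 10 / (142 * 0.07))
})

test_that("metrics are scale-equivariant and shift-invariant", {
  set.seed(5)
  for (i in 1:10) {
    g <- gen_area_series(worm_scene_spec(n_frames = 100,
                                         contraction_amplitude = runif(1, 40, 150),
                                         baseline_area = 500,
                                         contraction_freq_hz = runif(1, 0.5, 2),
                                         area_noise_sd = 2, seed = i))
    a <- g$series$area_px2
    base <- analyze_area_series(area_series(a, 0.07), 3, 1)
    scaled <- analyze_area_series(area_series(3 * a, 0.07), 3, 3 * 1)
    shifted <- analyze_area_series(area_series(a + 250, 0.07), 3, 1)
    expect_identical(scaled$n_contractions, base$n_contractions)
    expect_equal(scaled$frequency_hz, base$frequency_hz)
    expect_equal(scaled$rate_of_change_px2, 3 * base$rate_of_change_px2)
    expect_identical(shifted$n_contractions, base$n_contractions)
    expect_equal(shifted$rate_of_change_px2, base$rate_of_change_px2)
    expect_equal(shifted$amplitudes_px2, base$amplitudes_px2)
  }
})

test_that("detector agrees with the brute-force enumeration on random series", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(10:150, 1)
    x <- random_test_series(n, sample(c("smooth", "walk", "noise"), 1))
    w <- sample(c(1L, 3L, 5L), 1)
    if (w > n) w <- 1L
    prom <- runif(1, 0, 2)
    dev <- deviation_series(area_series(x - min(x), 0.07))
    pk <- detect_peaks(dev, w, prom)
    ref <- oracle_peaks(dev$deviation_px2, w, prom)
    expect_identical(pk$lower_peak_frames, ref$lower)
    expect_identical(pk$upper_peak_frames, ref$upper)
  }
})

test_that("the full movie assay recovers ground truth and enforces QC", {
  mv <- gen_worm_movie(worm_scene_spec(n_frames = 143, pixel_noise_sd = 0,
                                       contraction_amplitude = 100,
                                       baseline_area = 350,
                                       contraction_freq_hz = 1, seed = 6))
  res <- run_contraction_assay(mv$stack)
  expect_identical(res$n_contractions, mv$truth$true_n_contractions)
  expect_identical(res$provenance$run_start, 1L)
  expect_identical(res$provenance$run_end, 143L)

  short <- gen_worm_movie(worm_scene_spec(n_frames = 42, pixel_noise_sd = 0,
                                          contraction_amplitude = 100,
                                          baseline_area = 350, seed = 6))
  expect_error(run_contraction_assay(short$stack), "full-body QC filter")
})
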