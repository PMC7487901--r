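test_that("identical seeds give bit-identical scenes and ground truth", {
  expect_identical(make_fret_scene(seed = 7), make_fret_scene(seed = 7))
  expect_identical(make_matrix_scene(degraded_fraction = 0.2, noise_sd = 10,
                                     seed = 7),
                   make_matrix_scene(degraded_fraction = 0.2, noise_sd = 10,
                                     seed = 7))
  expect_identical(make_puncta_scene(seed = 7), make_puncta_scene(seed = 7))
  expect_identical(make_track_set(seed = 7), make_track_set(seed = 7))
  expect_identical(make_wound_series(seed = 7), make_wound_series(seed = 7))
  expect_identical(make_cytometry_events(seed = 7),
                   make_cytometry_events(seed = 7))
  # different seeds differ
  expect_false(identical(make_puncta_scene(seed = 1)$image$pixels,
                         make_puncta_scene(seed = 2)$image$pixels))
})

test_that("noiseless FRET scenes reduce to their closed-form construction", {
  quiet <- list(poisson = FALSE, read_sd = 0)
  sc1 <- make_fret_scene(ratio_baseline = 1.0, noise = quiet, seed = 1)
  inside <- sc1$mask$pixels == 1
  expect_identical(sc1$images$fret$pixels[inside],
                   sc1$images$donor$pixels[inside])

  # background-free construction: the raw pixelwise quotient is the ratio
  sc16 <- make_fret_scene(ratio_baseline = 1.6, background_level = 0,
                          noise = quiet, seed = 1)
  inside <- sc16$mask$pixels == 1
  expect_equal(sc16$images$fret$pixels[inside] /
                 sc16$images$donor$pixels[inside],
               rep(1.6, sum(inside)), tolerance = 1e-12)
  expect_equal(sc16$truth$mean_ratio, 1.6)
  expect_error(make_fret_scene(axes = c(200, 200)), "exceeds")
})

test_that("tail hotspot shifts the true mean ratio by its area share", {
  sc <- make_fret_scene(ratio_baseline = 1,
                        hotspot = list(factor = 2, fraction = 0.1),
                        noise = list(poisson = FALSE, read_sd = 0), seed = 3)
  inside <- sc$mask$pixels == 1
  # brute-force mean of the generated ratio map over mask pixels
  oracle <- mean(sc$truth$ratio_map[inside])
  expect_equal(sc$truth$mean_ratio, oracle)
  n_hot <- round(0.1 * sum(inside))
  expect_equal(oracle, 1 + n_hot / sum(inside) * (2 - 1), tolerance = 1e-12)
  expect_equal(oracle, 1.1, tolerance = 0.01)
})

test_that("matrix scenes honour spot depth and requested degraded fraction", {
  sc0 <- make_matrix_scene(noise_sd = 0, seed = 1)
  expect_true(all(sc0$matrix$pixels == sc0$truth$matrix_level))

  sc1 <- make_matrix_scene(spots = list(list(center = c(96, 96), radius = 4,
                                             depth = 1)),
                           noise_sd = 0, seed = 1)
  expect_identical(sc1$matrix$pixels[96, 96], 0)

  sc25 <- make_matrix_scene(degraded_fraction = 0.25, noise_sd = 0, seed = 5)
  fp <- sc25$mask$pixels == 1
  realized <- sum(sc25$truth$depth_map[fp] > 0)   # count map pixels
  expect_lte(abs(realized - round(0.25 * sum(fp))), 1)
  expect_equal(sc25$truth$degraded_fraction, realized / sum(fp))
})

test_that("puncta scenes place the stated spots and nothing else", {
  sc0 <- make_puncta_scene(n_puncta = 0, noise_sd = 0, seed = 1)
  expect_true(all(sc0$image$pixels == 100))

  sc <- make_puncta_scene(n_puncta = 12, noise_sd = 0, seed = 2)
  mx <- brute_local_maxima(sc$image$pixels, floor = 100 + 1)
  expect_identical(nrow(mx), 12L)

  bright <- make_puncta_scene(n_puncta = 12, noise_sd = 0, peak = 1000,
                              seed = 2)
  expect_identical(bright$truth$centers, sc$truth$centers)

  expect_error(make_puncta_scene(shape = c(64, 64), n_puncta = 50,
                                 radius_range = c(4, 6), max_tries = 50,
                                 seed = 1),
               "placement")
})

test_that("track sets have exact closed-form truth in degenerate settings", {
  still <- make_track_set(n_cells = 3, n_frames = 10, step_um = 0, seed = 1)
  expect_true(all(still$truth$per_track$total_path_um == 0))
  xs <- tapply(still$tracks$x, still$tracks$track_id, function(v)
    diff(range(v)))
  expect_true(all(unlist(xs) == 0))

  straight <- make_track_set(n_cells = 2, n_frames = 50, step_um = 0.4,
                             persistence = 1, seed = 2)
  expect_equal(straight$truth$per_track$net_um,
               rep(0.4 * 49, 2), tolerance = 1e-9)
  expect_equal(straight$truth$per_track$total_path_um, rep(0.4 * 49, 2))

  ctrl <- make_track_set(n_frames = 120, frame_interval_min = 1,
                         step_um = 0.3, seed = 3)
  expect_equal(unique(ctrl$truth$per_track$speed_um_min), 0.3)
})

test_that("wound series follow w(t) = max(0, w0 - rate t)", {
  frozen <- make_wound_series(rate_um_hr = 0, times_hr = c(0, 24, 48),
                              seed = 1)
  expect_identical(frozen$masks[[1]], frozen$masks[[2]])
  expect_identical(frozen$masks[[1]], frozen$masks[[3]])

  sc <- make_wound_series(width0_um = 500, rate_um_hr = 5,
                          times_hr = c(0, 48), seed = 2)
  expect_equal(sc$truth$widths_um, c(500, 260))

  smooth <- make_wound_series(roughness_um = 0, seed = 3)
  w <- wound_widths(smooth$masks[[1]], pixel_size_um = 2)
  expect_identical(length(unique(w)), 1L)
})

test_that("cytometry event mixtures match their truth labels", {
  tight <- make_cytometry_events(n_events = 500, fractions = c(1, 0, 0),
                                 cv = 0.001, seed = 1)
  expect_true(all(abs(tight$events$pi / tight$truth$peak_2n - 1) < 0.01))

  mix <- make_cytometry_events(n_events = 10000,
                               fractions = c(0.6, 0.2, 0.2), seed = 2)
  # truth label counts within binomial 99% bounds of the requested fractions
  for (i in 1:3) {
    p <- c(0.6, 0.2, 0.2)[i]
    expect_lt(abs(mix$truth$fractions[i] - p),
              2.576 * sqrt(p * (1 - p) / 10000))
  }

  live_only <- make_annexin_events(n_events = 400, fractions = c(1, 0, 0),
                                   seed = 3)
  cl <- classify_annexin_pi(live_only$events)
  expect_identical(unname(cl$fractions[["live"]]), 1)
})

test_that("gel lane truth carries exposure-invariant fold structure", {
  eq <- make_gel_lanes(c(5, 5, 5), c(2, 2, 2), seed = 1)
  expect_true(all(eq$truth$normalized / eq$truth$normalized[1] == 1))

  dbl <- make_gel_lanes(c(5, 10), c(2, 2), seed = 1)
  expect_equal(dbl$truth$normalized[2] / dbl$truth$normalized[1], 2)

  base <- make_gel_lanes(c(5, 10), c(2, 4), noise_cv = 0, seed = 1)
  exposed <- make_gel_lanes(3 * c(5, 10), 3 * c(2, 4), noise_cv = 0, seed = 1)
  f1 <- densitometry_fold(base$bands, "lane1")$fold
  f2 <- densitometry_fold(exposed$bands, "lane1")$fold
  expect_identical(f1, f2)
})
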