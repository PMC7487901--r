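test_that("clahe is bounded, idempotent on constants, and boosts local contrast", {
  expect_true(all(clahe(matrix(42, 64, 64)) ==
                    clahe(matrix(42, 64, 64))[1, 1]))
  set.seed(5)
  img <- matrix(runif(128 * 128, 0, 4000), 128)
  out <- clahe(img)
  expect_gte(min(out), 0); expect_lte(max(out), 1)
  expect_error(clahe(matrix(1:36, 6)), "tile larger")
  expect_error(clahe(img, tile_px = 4), ">= 8")
  expect_error(clahe(img, clip_limit = 0), "clip_limit")

  # dim spots on a strong illumination ramp: CLAHE raises spot contrast
  sc <- make_puncta_scene(n_puncta = 6, peak = 60, background = 200,
                          gradient_amp = 1500, noise_sd = 3, seed = 9)
  raw <- sc$image$pixels
  enh <- clahe(raw, tile_px = 32)
  contrast <- function(m) {
    ctr <- round(sc$truth$centers)
    spot <- m[ctr]
    local_bg <- vapply(seq_len(nrow(ctr)), function(i)
      stats::median(m[ctr[i, 1] + (-9:9), ctr[i, 2] + (-9:9)]), numeric(1))
    mean(spot - local_bg) / diff(range(m))
  }
  expect_gte(contrast(enh), contrast(raw))
})

test_that("LoG response vanishes on constants and ramps and peaks at r/sqrt(2)", {
  expect_lt(max(abs(log_response(matrix(9, 40, 40), 2))), 1e-9)
  ramp <- matrix(seq_len(60), 60, 60, byrow = TRUE) * 5
  inner <- log_response(ramp, 2)[20:40, 20:40]
  expect_lt(max(abs(inner)), 1e-8)
  expect_error(log_response(ramp, 0.2), ">= 0.5")

  r_spot <- 4
  sc <- make_puncta_scene(n_puncta = 1, radius_range = c(r_spot, r_spot),
                          noise_sd = 0, seed = 3)
  ctr <- round(sc$truth$centers[1, ])
  sig_grid <- seq(1, 6, by = 0.25)
  resp_at_ctr <- vapply(sig_grid, function(s)
    log_response(sc$image$pixels, s)[ctr[1], ctr[2]], numeric(1))
  best <- sig_grid[which.max(resp_at_ctr)]
  expect_lt(abs(best - r_spot / sqrt(2)), 0.3)
})

test_that("detection finds exactly the planted spots and respects filters", {
  set.seed(21)
  blank <- matrix(abs(rnorm(128 * 128, 500, 40)), 128)
  expect_identical(nrow(detect_puncta(blank, sigma_px = 2, k_mad = 5)$puncta),
                   0L)

  for (s in 1:5) {
    sc <- make_puncta_scene(n_puncta = 12, peak = 500, noise_sd = 100,
                            seed = s)
    ps <- detect_puncta(sc$image, sigma_px = 2)
    expect_identical(nrow(ps$puncta), 12L)
    expect_all_lt(nearest_truth_dist(ps$puncta, sc$truth$centers), 1)
  }

  sc <- make_puncta_scene(n_puncta = 12, peak = 500, noise_sd = 100, seed = 1)
  none <- detect_puncta(sc$image, sigma_px = 2, max_area_px = 2)
  expect_identical(nrow(none$puncta), 0L)

  filt <- detect_puncta(sc$image, sigma_px = 2, min_area_px = 6,
                        max_area_px = 60)
  expect_true(all(filt$puncta$supra_px >= 6 & filt$puncta$supra_px <= 60))
})

test_that("detection is invariant under global multiplicative scaling", {
  sc <- make_puncta_scene(n_puncta = 10, noise_sd = 50, seed = 13)
  base <- detect_puncta(sc$image, sigma_px = 2)$puncta
  for (k in c(0.5, 10)) {
    scaled <- detect_puncta(sc$image$pixels * k, sigma_px = 2)$puncta
    expect_identical(nrow(scaled), nrow(base))
    expect_equal(scaled$row, base$row, tolerance = 1e-9)
    expect_equal(scaled$area_px, base$area_px, tolerance = 1e-9)
  }
})

test_that("adhesion area fold compares mean punctum areas to control", {
  mk <- function(areas) {
    n <- length(areas)
    puncta_set(data.frame(id = seq_len(n), row = rep(1, n), col = rep(1, n),
                          area_px = areas, area_um2 = areas,
                          mean_int = rep(1, n)))
  }
  expect_identical(adhesion_area_fold(mk(c(10, 10)), mk(c(5, 5))), 2)
  expect_identical(adhesion_area_fold(mk(c(3, 5)), mk(c(3, 5))), 1)
  expect_identical(
    adhesion_area_fold(list(mk(c(4, 4)), mk(8)), list(mk(c(2, 2)), mk(4)),
                       mode = "per_cell_total"),
    2)
  expect_error(adhesion_area_fold(mk(5), mk(numeric(0))), "control")

  # brute-force oracle from truth lists: doubling radii quadruples mean area
  sc <- make_puncta_scene(n_puncta = 8, radius_range = c(4, 6), seed = 31,
                          min_sep = 40)
  ctrl_truth <- mk(pi * (sc$truth$radii / 2)^2)
  samp_truth <- mk(pi * sc$truth$radii^2)
  expect_equal(adhesion_area_fold(samp_truth, ctrl_truth), 4)
})

test_that("invadopodia are counted as absolute per-cell numbers", {
  mk <- function(n) puncta_set(data.frame(
    id = seq_len(n), row = rep(1, n), col = rep(1, n), area_px = rep(1, n),
    area_um2 = rep(1, n), mean_int = rep(1, n)))
  expect_identical(invadopodia_count(list(mk(0), mk(0)))$mean, 0)
  cnt <- invadopodia_count(list(mk(3), mk(5), mk(7)))
  expect_identical(cnt$per_cell, c(3L, 5L, 7L))
  expect_identical(cnt$mean, 5)

  sets <- lapply(1:12, function(s) {
    sc <- make_puncta_scene(n_puncta = 6, peak = 500, noise_sd = 100,
                            seed = 50 + s)
    detect_puncta(sc$image, sigma_px = 2)
  })
  expect_lt(abs(invadopodia_count(sets)$mean - 6) / 6, 0.05)
})

test_that("line profiles interpolate along the segment and reverse cleanly", {
  flat <- line_profile(matrix(7, 30, 30), c(5, 5), c(25, 25))
  expect_true(all(flat$intensity == 7))
  expect_error(line_profile(matrix(7, 30, 30), c(0, 5), c(25, 25)), "inside")

  sc <- make_puncta_scene(centers = matrix(c(96, 96), 1), radii = 4,
                          noise_sd = 0, seed = 17)
  ctr <- sc$truth$centers[1, ]
  p0 <- ctr + c(-20, -20); p1 <- ctr + c(20, 20)
  prof <- line_profile(list(tks4 = sc$image), p0, p1, sampling_px = 0.5)
  # the peak lies where the segment passes closest to the spot centre
  expect_equal(prof$distance_px[which.max(prof$tks4)],
               sqrt(sum((ctr - p0)^2)), tolerance = 1)
  rev_prof <- line_profile(list(tks4 = sc$image), p1, p0, sampling_px = 0.5)
  expect_equal(rev(rev_prof$tks4), prof$tks4, tolerance = 1e-9)
})
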