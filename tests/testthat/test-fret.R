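quiet <- list(poisson = FALSE, read_sd = 0)

test_that("background correction subtracts the background median and clips", {
  u <- raster_img(matrix(50, 20, 20), 1)
  bg <- cell_mask(matrix(1, 20, 20))
  expect_true(all(correct_background(u, bg)$pixels == 0))

  img <- matrix(50, 40, 40); img[15:25, 15:25] <- 150
  bgm <- cell_mask(img == 50)
  corr <- correct_background(raster_img(img, 1), bgm)
  expect_true(all(corr$pixels[15:25, 15:25] == 100))
  expect_true(all(corr$pixels[img == 50] == 0))
  expect_error(correct_background(u, cell_mask(matrix(0, 20, 20))), "empty")
})

test_that("auto background correction recovers a known background level", {
  sc <- make_fret_scene(background_level = 120,
                        noise = list(poisson = FALSE, read_sd = 15), seed = 4)
  corr <- correct_background(sc$images$donor)
  outside <- sc$mask$pixels == 0
  expect_lt(abs(mean(corr$pixels[outside])), 15)
})

test_that("cell masking keeps the largest filled component", {
  sc <- make_fret_scene(noise = quiet, seed = 1)
  m <- make_cell_mask(sc$images$acceptor)
  truth_area <- sc$truth$cell_area_px
  # boundary ring allowance: <= 2 px times an ellipse-perimeter estimate
  a <- c(35, 52)
  perim <- pi * (3 * sum(a) - sqrt((3 * a[1] + a[2]) * (a[1] + 3 * a[2])))
  expect_lt(abs(sum(m$pixels) - truth_area), 2 * perim)

  expect_error(make_cell_mask(raster_img(matrix(7, 30, 30), 1)), "uniform")

  two <- matrix(0, 80, 80)
  two[10:40, 10:40] <- 100   # 31x31
  two[60:68, 60:68] <- 100   # 9x9
  mk <- make_cell_mask(raster_img(two, 1), min_area_px = 10)
  expect_true(all(mk$pixels[60:68, 60:68] == 0))
  expect_true(all(mk$pixels[10:40, 10:40] == 1))
})

test_that("ratio image is the pixelwise FRET/donor mean over the mask", {
  set.seed(11)
  d <- matrix(80 + runif(400) * 40, 20)
  set_id <- fret_image_set(raster_img(d, 1), raster_img(d, 1),
                           raster_img(d, 1))
  ri <- ratio_image(set_id, cell_mask(matrix(1, 20, 20)), donor_floor = 0)
  expect_identical(ri$mean_ratio, 1)   # identity holds under any "noise"

  sc <- make_fret_scene(ratio_baseline = 2, noise = quiet, seed = 2)
  set2 <- fret_image_set(correct_background(sc$images$donor,
                                            cell_mask(sc$mask$pixels == 0)),
                         correct_background(sc$images$fret,
                                            cell_mask(sc$mask$pixels == 0)),
                         sc$images$acceptor)
  ri2 <- ratio_image(set2, sc$mask, donor_floor = 0)
  expect_equal(ri2$mean_ratio, 2)
  # shrinking the donor floor on noiseless scenes changes nothing
  ri2b <- ratio_image(set2, sc$mask, donor_floor = 500)
  expect_equal(ri2b$mean_ratio, ri2$mean_ratio)
  expect_error(ratio_image(set2, sc$mask, donor_floor = 1e9), "donor floor")
})

test_that("Poisson-noise scenes recover the true mean ratio within 5%", {
  sc <- make_fret_scene(ratio_baseline = 1.5,
                        noise = list(poisson = TRUE, read_sd = 20), seed = 6)
  set <- fret_image_set(correct_background(sc$images$donor),
                        correct_background(sc$images$fret),
                        sc$images$acceptor)
  ri <- ratio_image(set, make_cell_mask(sc$images$acceptor))
  expect_lt(abs(ri$mean_ratio - 1.5) / 1.5, 0.05)
})

test_that("the ratio is exactly invariant to joint exposure rescaling", {
  sc <- make_fret_scene(ratio_baseline = 1.5,
                        noise = list(poisson = TRUE, read_sd = 20), seed = 8)
  m <- make_cell_mask(sc$images$acceptor)
  base <- ratio_image(fret_image_set(sc$images$donor, sc$images$fret,
                                     sc$images$acceptor), m, donor_floor = 10)
  for (k in c(0.5, 3, 10)) {
    scaled <- fret_image_set(
      raster_img(sc$images$donor$pixels * k, 1),
      raster_img(sc$images$fret$pixels * k, 1),
      sc$images$acceptor)
    rk <- ratio_image(scaled, m, donor_floor = 10 * k)
    expect_equal(rk$mean_ratio, base$mean_ratio, tolerance = 1e-12)
  }
})

test_that("fold change to control behaves like a ratio of condition means", {
  expect_identical(fret_fold_change(c(1.2, 1.4), c(1.2, 1.4)), 1)
  expect_identical(fret_fold_change(c(2, 2), c(1, 1)), 2)
  expect_error(fret_fold_change(numeric(0), 1), "at least one")
  expect_error(fret_fold_change(c(1, 2), c(-1, 1)), "> 0")
})
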