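test_that("cell-cycle gating follows the ploidy definitions", {
  pure <- rep(200, 500)
  g <- gate_cell_cycle(pure)
  expect_equal(unname(g$fractions), c(1, 0, 0))
  expect_equal(g$peak_2n, 200, tolerance = 0.02)

  # events at exactly 3n (> 2n, < 4n) are S phase
  v <- c(rnorm(400, 200, 2), rep(300, 100))
  g3 <- gate_cell_cycle(v)
  expect_true(all(g3$labels[v == 300] == "s"))
  expect_equal(sum(g3$fractions), 1)
  expect_equal(sum(g3$fractions_raw), 1)

  expect_error(gate_cell_cycle(rep(200, 50)), "at least 100")
})

test_that("gating recovers simulated mixtures within 0.02", {
  sim <- make_cytometry_events(n_events = 10000,
                               fractions = c(0.6, 0.2, 0.2), cv = 0.05,
                               seed = 12)
  g <- gate_cell_cycle(sim$events$pi)
  expect_true(all(abs(g$fractions - sim$truth$fractions) < 0.02))
  # a 4n-dominated sample still locates the 2n peak at half position
  sim2 <- make_cytometry_events(n_events = 5000,
                                fractions = c(0.25, 0.1, 0.65), cv = 0.05,
                                seed = 13)
  g2 <- gate_cell_cycle(sim2$events$pi)
  expect_equal(g2$peak_2n, 200, tolerance = 0.1)
  expect_true(all(abs(g2$fractions - sim2$truth$fractions) < 0.03))
})

test_that("Annexin/PI quadrant rules classify the four populations", {
  thr <- c(annexin = 100, pi = 100)
  ev <- data.frame(annexin = c(1, 500, 500, 1), pi = c(1, 1, 500, 500))
  cl <- classify_annexin_pi(ev, thr)
  expect_identical(cl$labels,
                   c("live", "early_apoptotic", "necrotic", "other"))
  expect_equal(sum(cl$fractions), 1)

  origin <- data.frame(annexin = rep(1, 50), pi = rep(1, 50))
  expect_identical(unname(classify_annexin_pi(origin, thr)$fractions[["live"]]),
                   1)

  sim <- make_annexin_events(n_events = 10000,
                             fractions = c(0.7, 0.2, 0.1), seed = 14)
  cl2 <- classify_annexin_pi(sim$events)
  expect_true(all(abs(cl2$fractions[1:3] - sim$truth$fractions) < 0.02))
})

test_that("densitometry folds are loading-normalized and exposure invariant", {
  b <- data.frame(lane = c("luc", "kd"), band = c(10, 10),
                  loading = c(5, 5))
  expect_equal(densitometry_fold(b, "luc")$fold, c(1, 1))

  b25 <- data.frame(lane = c("luc", "kd"), band = c(10, 25),
                    loading = c(5, 5))
  f <- densitometry_fold(b25, "luc")
  expect_equal(f$fold[f$lane == "kd"], 2.5)

  b3 <- b25; b3$band <- b3$band * 3; b3$loading <- b3$loading * 3
  expect_identical(densitometry_fold(b3, "luc")$fold,
                   densitometry_fold(b25, "luc")$fold)

  bz <- b25; bz$loading[1] <- 0
  expect_error(densitometry_fold(bz, "luc"), "> 0")
  expect_error(densitometry_fold(b25, "nope"), "not present")
})

test_that("sphere metrics use the circular closed forms", {
  m <- sphere_metrics(100)
  expect_equal(m$area_um2, 7853.98, tolerance = 1e-5)
  expect_equal(m$volume_um3, 523598.8, tolerance = 1e-6)

  m2 <- sphere_metrics(200)
  expect_equal(m2$area_um2 / m$area_um2, 4)
  expect_equal(m2$volume_um3 / m$volume_um3, 8)

  disk <- rhoquant:::.ellipse_mask(c(128, 128), c(64, 64), c(50, 50))
  md <- sphere_metrics(mask = cell_mask(disk), pixel_size_um = 1)
  # equivalent diameter oracle straight from the pixel count
  expect_equal(md$diameter_um, 2 * sqrt(sum(disk) / pi))
  expect_lt(abs(md$diameter_um - 100) / 100, 0.01)
  expect_error(sphere_metrics(-1), "> 0")
})

test_that("tissue mean intensity compares fixed-area frames between groups", {
  frames <- c(replicate(3, matrix(400, 20, 20), simplify = FALSE),
              replicate(3, matrix(100, 20, 20), simplify = FALSE))
  res <- tissue_mean_intensity(frames, groups = rep(c("normal", "tumor"),
                                                    each = 3))
  expect_true(all(res$mean_intensity == rep(c(400, 100), each = 3)))
  expect_equal(attr(res, "group_fold"), 4)

  res_rev <- tissue_mean_intensity(rev(frames),
                                   groups = rep(c("tumor", "normal"),
                                                each = 3))
  expect_equal(attr(res, "group_fold") * attr(res_rev, "group_fold"), 1)

  expect_error(tissue_mean_intensity(list(matrix(1, 2, 2), matrix(1, 3, 3))),
               "shape")
})
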