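test_that("config invariants are enforced", {
  expect_error(landscape_config(extent_m = 10), "smaller than one cell")
  expect_error(landscape_config(extent_m = 150), "whole cells")
  expect_error(landscape_config(ba_sd = -1), "sds")
})

test_that("identical config and seed give bit-identical landscapes", {
  a <- simulate_landscape(tiny_config(seed = 7))
  b <- simulate_landscape(tiny_config(seed = 7))
  expect_identical(a$stems, b$stems)
  expect_identical(a$truth, b$truth)
  expect_identical(a$rasters$chm$values, b$rasters$chm$values)
  expect_identical(a$rasters$cir$nir$values, b$rasters$cir$nir$values)
  c <- simulate_landscape(tiny_config(seed = 8))
  expect_false(identical(a$stems, c$stems))
})

test_that("truth fields are consistent with the stem map", {
  L <- simulate_landscape(tiny_config(seed = 2), rasters = FALSE)
  a_ha <- L$grid$cell_size_m^2 / 1e4
  for (cell in sample(L$truth$cell, 20)) {
    st <- L$stems[L$stems$cell == cell, ]
    expect_equal(L$truth$ba[cell],
                 sum(pi * (st$dbh_cm / 200)^2) / a_ha, tolerance = 1e-9)
    expect_equal(L$truth$tph[cell], nrow(st) / a_ha, tolerance = 1e-9)
  }
  expect_true(all(L$truth$ba >= 0))
  expect_true(all(L$truth$pcon >= 0 & L$truth$pcon <= 100))
  expect_true(all(L$stems$dbh_cm > 0))
  expect_true(all(L$stems$height_m > 0))
  expect_true(all(L$stems$x >= 0 & L$stems$x <= 160))
  expect_true(all(L$stems$y >= 0 & L$stems$y <= 160))
})

test_that("noiseless degenerate config gives identical cells and exact band models", {
  cfg <- landscape_config(extent_m = 120, cell_size_m = 20, ba_sd = 0,
                          tph_sd = 0, conifer_logit_sd = 0,
                          image_noise_sd = 0, chm_res_m = 1, dem_res_m = 2,
                          img_res_m = 2, tph_mean = 600, seed = 4)
  L <- simulate_landscape(cfg, rasters = TRUE, crowns = FALSE)
  # bands are identical everywhere: expectation depends only on the
  # (constant) target fields
  expect_equal(diff(range(L$rasters$cir$nir$values)), 0)
  expect_equal(diff(range(L$rasters$rgb$blue$values)), 0)
  # with noise but varying fields, band means are exactly affine in
  # (cover, pcon): R^2 = 1 on noiseless bands
  cfg2 <- landscape_config(extent_m = 200, cell_size_m = 20,
                           image_noise_sd = 0, chm_res_m = 1, dem_res_m = 2,
                           img_res_m = 2, tph_mean = 600,
                           spatial_corr_range_m = 60, seed = 5)
  L2 <- simulate_landscape(cfg2, rasters = TRUE, crowns = FALSE)
  cf <- summarize_cells(L2$grid, cir = L2$rasters$cir)
  fit <- lm(cf$cir_nir_px_mean ~ I(1 - exp(-0.03 * ba)) + pcon,
            data = cbind(cf, L2$targets[, c("ba", "pcon")]))
  expect_gt(suppressWarnings(summary(fit))$r.squared, 1 - 1e-9)
})

test_that("spatial correlation range is recovered by a variogram oracle", {
  rng <- function(range_m, seed) {
    cfg <- landscape_config(extent_m = 600, cell_size_m = 20,
                            spatial_corr_range_m = range_m, seed = seed)
    set.seed(seed)
    nr <- 30
    z <- stratiforest:::sim_grf(nr, nr, 20, range_m)
    cc <- expand.grid(x = (1:nr - 0.5) * 20, y = (1:nr - 0.5) * 20)
    oracle_variogram_range(cc$x, cc$y, as.vector(z), max_lag = 300)
  }
  long <- vapply(1:3, function(s) rng(200, s), 0)
  short <- vapply(1:3, function(s) rng(20, s), 0)
  expect_gt(min(long), max(short))
})

test_that("limiting distance matches the closed-form prism relation", {
  # BAF = 2500 (D/R)^2  =>  R = 50 D / sqrt(BAF), D in m
  expect_equal(limiting_distance(40, 4.6), 50 * 0.4 / sqrt(4.6))
  expect_equal(limiting_distance(40, 4.6), 9.325, tolerance = 1e-3)
  expect_equal(limiting_distance(80, 4.6), 2 * limiting_distance(40, 4.6))
  expect_lt(limiting_distance(1e-9, 4.6), 1e-9)
  expect_error(limiting_distance(0, 4.6), "positive")
  expect_error(limiting_distance(40, -1), "positive")
})

test_that("prism tallies equal the brute-force limiting-distance scan", {
  L <- simulate_landscape(tiny_config(seed = 3), rasters = FALSE)
  set.seed(9)
  for (i in 1:25) {
    ctr <- runif(2, 10, 150)
    p <- simulate_prism_plot(L$stems, ctr, baf = 4.6, min_dbh_cm = 14,
                             gps_error_95_m = 0)
    want <- oracle_tally(L$stems, ctr, 4.6, 14)
    expect_equal(nrow(p$tally), length(want))
    expect_equal(sort(p$tally$dbh_cm), sort(L$stems$dbh_cm[want]))
  }
})

test_that("single-tree threshold cases fall exactly at the limiting distance", {
  one <- data.frame(x = 9.0, y = 0, species = "CON", conifer = TRUE,
                    dbh_cm = 40, height_m = 30, dead = FALSE, cell = 1L)
  p_in <- simulate_prism_plot(one, c(0, 0), baf = 4.6, min_dbh_cm = 14)
  expect_equal(nrow(p_in$tally), 1L)   # 9.0 < 9.325
  one$x <- 9.5
  p_out <- simulate_prism_plot(one, c(0, 0), baf = 4.6, min_dbh_cm = 14)
  expect_equal(nrow(p_out$tally), 0L)
  empty <- one[0, ]
  p_e <- simulate_prism_plot(empty, c(0, 0), baf = 4.6, min_dbh_cm = 14)
  expect_equal(nrow(p_e$tally), 0L)
})

test_that("GPS jitter is calibrated to the 95% radius", {
  set.seed(42)
  sig <- stratiforest:::gps_sigma(10)
  r <- sqrt(rnorm(10000, 0, sig)^2 + rnorm(10000, 0, sig)^2)
  expect_equal(mean(r <= 10), 0.95, tolerance = 0.01)
  # and through the plot simulator itself
  one <- data.frame(x = 1e6, y = 1e6, species = "CON", conifer = TRUE,
                    dbh_cm = 40, height_m = 30, dead = FALSE, cell = 1L)
  set.seed(43)
  ctrs <- t(vapply(1:2000, function(i)
    simulate_prism_plot(one, c(0, 0), gps_error_95_m = 10)$center,
    numeric(2)))
  expect_equal(mean(sqrt(rowSums(ctrs^2)) <= 10), 0.95, tolerance = 0.02)
})
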