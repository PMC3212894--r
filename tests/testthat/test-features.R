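gauss_bump <- function(nr, nc, cx, cy, peak, width, cell = 1) {
  x <- (seq_len(nc) - 0.5) * cell
  y <- rev((seq_len(nr) - 0.5) * cell)
  peak * exp(-outer((y - cy)^2, (x - cx)^2, "+") / (2 * width^2))
}

test_that("watershed finds one crown per isolated maximum", {
  v <- gauss_bump(40, 40, 20, 20, peak = 20, width = 4)
  cs <- segment_crowns(raster_layer(v, cell_size = 1), min_height_m = 2,
                       smoothing_sigma_m = 1, min_area_m2 = 1)
  expect_equal(nrow(cs$crowns), 1L)
  expect_equal(cs$crowns$max_height_m, 20, tolerance = 0.05)
  expect_equal(cs$crowns$centroid_x, 20, tolerance = 1)

  two <- gauss_bump(60, 60, 15, 30, 20, 3) + gauss_bump(60, 60, 45, 30, 18, 3)
  cs2 <- segment_crowns(raster_layer(two, cell_size = 1), 2, 1, 1)
  expect_equal(nrow(cs2$crowns), 2L)

  flat <- raster_layer(matrix(0, 30, 30), cell_size = 1)
  cs3 <- segment_crowns(flat, 2, 1, 1)
  expect_equal(nrow(cs3$crowns), 0L)

  allna <- raster_layer(matrix(NA_real_, 10, 10), cell_size = 1)
  expect_warning(cs4 <- segment_crowns(allna, 2, 1, 1), "nodata")
  expect_equal(nrow(cs4$crowns), 0L)
})

test_that("crowns partition the above-threshold canopy without overlap", {
  set.seed(21)
  L <- simulate_landscape(tiny_config(seed = 21))
  lab <- L$crowns$label$values
  chm <- L$rasters$chm$values
  sm <- stratiforest:::smooth_gaussian(chm, 1)
  # every labelled pixel is canopy; labels are a disjoint partition by
  # construction (one label per pixel) and each crown is one seed's basin
  expect_true(all(sm[lab > 0] >= 0))
  expect_equal(sum(L$crowns$crowns$n_px), sum(lab > 0))
  expect_gte(min(L$crowns$crowns$area_m2), 1)
})

test_that("image_summaries matches direct recomputation on arbitrary windows", {
  set.seed(5)
  w <- matrix(rnorm(64), 8, 8)
  st <- image_summaries(w)
  o <- oracle_stats(as.numeric(w))
  for (nm in names(o))
    expect_equal(unname(st[paste0("px_", nm)]), o[[nm]], tolerance = 1e-12,
                 label = nm)
  expect_equal(unname(st["hist_p25"]),
               unname(quantile(as.numeric(w), 0.25)), tolerance = 1e-12)
})

test_that("image_summaries degenerate windows", {
  cst <- matrix(3.3, 6, 6)
  st <- image_summaries(cst)
  expect_equal(unname(st[c("px_var", "px_skew", "px_kurt", "px_entropy",
                           "px_mad", "px_medad")]), rep(0, 6))
  half <- matrix(rep(c(0, 1), each = 18), 6, 6)
  st2 <- image_summaries(half)
  expect_equal(unname(st2["px_mean"]), 0.5)
  expect_equal(unname(st2["px_entropy"]), 1)  # 1 bit
  expect_error(image_summaries(matrix(0, 3, 5)), "4 x 4")
})

test_that("cell summaries honour the definitional examples", {
  g <- grid_spec(xmin = 0, ymax = 40, cell_size_m = 20, n_rows = 2,
                 n_cols = 2)
  cst <- raster_layer(matrix(250, 40, 40), cell_size = 1, ymax = 40)
  cf <- summarize_cells(g, dem = cst)
  expect_equal(cf$elev_var, rep(0, 4))
  expect_equal(cf$elev_mean, rep(250, 4))
  expect_equal(cf$plane_dep, rep(0, 4), tolerance = 1e-9)

  # uniform IR/red -> NDVI = (0.6-0.2)/(0.6+0.2) = 0.5 in every cell
  cir <- list(nir = raster_layer(matrix(0.6, 40, 40), cell_size = 1,
                                 ymax = 40),
              red = raster_layer(matrix(0.2, 40, 40), cell_size = 1,
                                 ymax = 40),
              green = raster_layer(matrix(0.3, 40, 40), cell_size = 1,
                                   ymax = 40))
  cf2 <- summarize_cells(g, cir = cir)
  expect_equal(cf2$ndvi, rep(0.5, 4))
  expect_equal(cf2$ir_red_ratio, rep(3, 4))
})

test_that("crown closure equals the covered-area share and conserves mass", {
  g <- grid_spec(xmin = 0, ymax = 40, cell_size_m = 20, n_rows = 2,
                 n_cols = 2)
  # crowns covering exactly the west half of every cell: tall west strip
  v <- matrix(0, 40, 40)
  v[, 1:10] <- 20  # west 10 m of the west cells
  cs <- segment_crowns(raster_layer(v, cell_size = 1, ymax = 40),
                       min_height_m = 2, smoothing_sigma_m = 0.5,
                       min_area_m2 = 1)
  cf <- summarize_cells(g, chm = raster_layer(v, cell_size = 1, ymax = 40),
                        crowns = cs)
  # closure 50% in the two west cells, 0 in the east cells
  expect_equal(sort(unique(round(cf$crown_closure))), c(0, 50))
  # mass conservation: sum(cell area * closure) == total crown area
  tot <- sum(400 * cf$crown_closure / 100)
  expect_equal(tot, sum(cs$crowns$area_m2), tolerance = 0.001 * tot)
})

test_that("aspect is treated circularly", {
  # constant aspect ~359 deg vs ~1 deg: circular variance must be ~0
  n <- 40
  ramp <- outer(rep(1, n), seq(0, 0.02 * (n - 1), by = 0.02))  # east-rising
  twist <- outer(seq(0, 0.001 * (n - 1), by = 0.001), rep(1, n))
  dem <- raster_layer(ramp + twist, cell_size = 1, ymax = n)
  g <- grid_spec(xmin = 0, ymax = n, cell_size_m = 20, n_rows = 2,
                 n_cols = 2)
  cf <- summarize_cells(g, dem = dem)
  expect_true(all(cf$aspect_cvar < 1e-4))
})

test_that("CRS mismatch is a hard error and resummarization is deterministic", {
  g <- grid_spec(xmin = 0, ymax = 40, cell_size_m = 20, n_rows = 2,
                 n_cols = 2, crs = "utm10")
  r <- raster_layer(matrix(1, 40, 40), cell_size = 1, ymax = 40,
                    crs = "wgs84")
  expect_error(summarize_cells(g, dem = r), "CRS mismatch")
  L <- simulate_landscape(tiny_config(seed = 6))
  a <- summarize_cells(L$grid, dem = L$rasters$dem, chm = L$rasters$chm,
                       crowns = L$crowns)
  b <- summarize_cells(L$grid, dem = L$rasters$dem, chm = L$rasters$chm,
                       crowns = L$crowns)
  expect_identical(a, b)
})
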