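#' Configuration for a synthetic forest landscape
#'
#' Defaults emulate a second/third-growth redwood--Douglas-fir--tanoak
#' property: per-plot basal area 0--116 m2/ha around a mean of 40.7, stem
#' densities with a long right tail, conifer share spanning the full range,
#' and GPS plot location error of 10 m at the 95th percentile. Raster products
#' default to the usual flight deliverables (0.5 m CHM, 1 m DEM, 0.6 m image
#' bands); coarser resolutions and smaller extents are the supported way to
#' scale experiments down.
#'
#' @param extent_m width/height of the square landscape (m); must divide into
#'   whole analysis cells.
#' @param cell_size_m analysis cell edge (m); 20 gives 0.04 ha cells.
#' @param spatial_corr_range_m practical range (m) of the exponential
#'   covariance of the latent fields (correlation ~ 0.05 at this distance).
#' @param ba_mean,ba_sd marginal mean and sd of true cell basal area (m2/ha).
#' @param tph_mean,tph_sd marginal mean and sd of true stems/ha.
#' @param conifer_logit_mean,conifer_logit_sd mean and sd of the latent
#'   conifer-share logit.
#' @param image_noise_sd per-pixel reflectance noise sd of the image bands.
#' @param gps_error_95_m radius containing 95% of plot-location error (m).
#' @param chm_res_m,dem_res_m,img_res_m raster resolutions (m).
#' @param min_dbh_cm smallest stem generated (cm). Defaults to the prism
#'   measurement threshold (14 cm) so the truth fields aggregate exactly the
#'   measurable stand; lower it to model sub-threshold stems, but then truth
#'   BA includes trees a cruise cannot see.
#' @param dead_fraction probability a stem is standing dead.
#' @param field_type `"grf"` for Gaussian-random-field structure (default) or
#'   `"block"` for square patches of side `block_size_m` with independent
#'   levels, used in grid-size recovery experiments where the generative
#'   scale must be known exactly.
#' @param block_size_m patch side (m) when `field_type = "block"`.
#' @param seed integer seed fixing every random draw.
#' @return a validated list of class `landscape_config`.
#' @export
landscape_config <- function(extent_m = c(640, 640), cell_size_m = 20,
                             spatial_corr_range_m = 200,
                             ba_mean = 40.7, ba_sd = 20,
                             tph_mean = 2339, tph_sd = 1500,
                             conifer_logit_mean = 0.27,
                             conifer_logit_sd = 1.5,
                             image_noise_sd = 0.02,
                             gps_error_95_m = 10,
                             chm_res_m = 0.5, dem_res_m = 1, img_res_m = 0.6,
                             min_dbh_cm = 14, dead_fraction = 0.05,
                             field_type = c("grf", "block"),
                             block_size_m = 30,
                             seed = 1L) {
  extent_m <- rep(as.numeric(extent_m), length.out = 2)
  field_type <- match.arg(field_type)
  cfg <- list(extent_m = extent_m, cell_size_m = cell_size_m,
              spatial_corr_range_m = spatial_corr_range_m,
              ba_mean = ba_mean, ba_sd = ba_sd,
              tph_mean = tph_mean, tph_sd = tph_sd,
              conifer_logit_mean = conifer_logit_mean,
              conifer_logit_sd = conifer_logit_sd,
              image_noise_sd = image_noise_sd,
              gps_error_95_m = gps_error_95_m,
              chm_res_m = chm_res_m, dem_res_m = dem_res_m,
              img_res_m = img_res_m,
              min_dbh_cm = min_dbh_cm, dead_fraction = dead_fraction,
              field_type = field_type, block_size_m = block_size_m,
              seed = as.integer(seed))
  class(cfg) <- "landscape_config"
  validate_landscape_config(cfg)
  cfg
}

validate_landscape_config <- function(cfg) {
  if (any(cfg$extent_m < cfg$cell_size_m))
    stop("invalid config: extent smaller than one cell", call. = FALSE)
  if (any(abs(cfg$extent_m / cfg$cell_size_m -
                round(cfg$extent_m / cfg$cell_size_m)) > 1e-9))
    stop("invalid config: extent must divide into whole cells", call. = FALSE)
  sds <- c(cfg$ba_sd, cfg$tph_sd, cfg$conifer_logit_sd, cfg$image_noise_sd)
  if (any(sds < 0)) stop("invalid config: sds must be >= 0", call. = FALSE)
  if (cfg$cell_size_m <= 0 || cfg$gps_error_95_m < 0)
    stop("invalid config: nonpositive size parameter", call. = FALSE)
  invisible(cfg)
}

# Stationary Gaussian random field on a regular grid, exponential covariance
# exp(-3 d / range) (practical-range convention), simulated by 2-D circulant
# embedding so large grids stay O(n log n). Negative embedding eigenvalues
# (possible for small tori) are clamped to zero, the standard approximation.
sim_grf <- function(n_rows, n_cols, cell_size, range_m) {
  if (range_m <= 0) return(matrix(rnorm(n_rows * n_cols), n_rows, n_cols))
  m <- 2 * n_rows
  n <- 2 * n_cols
  ry <- pmin(0:(m - 1), m - (0:(m - 1))) * cell_size
  rx <- pmin(0:(n - 1), n - (0:(n - 1))) * cell_size
  d <- sqrt(outer(ry^2, rx^2, "+"))
  lam <- Re(stats::fft(exp(-3 * d / range_m)))
  lam[lam < 0] <- 0
  eps <- matrix(complex(real = rnorm(m * n), imaginary = rnorm(m * n)), m, n)
  f <- stats::fft(sqrt(lam) * eps) / sqrt(m * n)
  Re(f)[seq_len(n_rows), seq_len(n_cols)]
}

# Square independent patches: a piecewise-constant standard-normal field.
sim_blocks <- function(n_rows, n_cols, cell_size, block_m) {
  nb <- max(1L, round(block_m / cell_size))
  br <- ceiling(n_rows / nb)
  bc <- ceiling(n_cols / nb)
  z <- matrix(rnorm(br * bc), br, bc)
  z[rep(seq_len(br), each = nb)[seq_len(n_rows)],
    rep(seq_len(bc), each = nb)[seq_len(n_cols)], drop = FALSE]
}

lognormal_pars <- function(mean, sd) {
  cv2 <- (sd / mean)^2
  s2 <- log1p(cv2)
  c(mu = log(mean) - s2 / 2, sigma = sqrt(s2))
}

# Chapman-Richards height allometry, conifers taller than hardwoods.
tree_height <- function(dbh_cm, conifer, noise_sd = 0.08) {
  asym <- ifelse(conifer, 65, 40)
  h <- 1.3 + asym * (1 - exp(-0.045 * dbh_cm))
  h * exp(rnorm(length(dbh_cm), 0, noise_sd))
}

crown_radius <- function(dbh_cm) 0.5 + 0.06 * dbh_cm

#' Simulate a synthetic forest landscape
#'
#' Generates latent spatially correlated fields (basal area and stem density
#' with log-normal marginals, conifer share through a logit link), draws a
#' stem map cell by cell (Poisson stem counts, gamma diameters around the
#' quadratic mean diameter implied by the cell's BA and TPH, Bernoulli conifer
#' flags, allometric heights), recomputes the per-cell truth table from the
#' realised stems, and optionally rasterises a CHM (crown envelopes), a smooth
#' DEM, and CIR/RGB image bands whose expectations are monotone in canopy
#' cover and conifer share.
#'
#' @param config a [landscape_config()].
#' @param rasters if `FALSE`, skip CHM/DEM/image rasterisation (fast mode for
#'   sampling experiments that only need stems and truth).
#' @param crowns if `TRUE` (and `rasters`), also segment crowns from the
#'   simulated CHM with [segment_crowns()], mirroring the vendor deliverable.
#' @return list of class `landscape` with elements `config`, `grid`
#'   ([grid_spec()]), `stems` (data.frame), `truth` (per-cell data.frame
#'   recomputed from the realised stems), `targets` (the latent per-cell
#'   expectation fields the stems were drawn from), `rasters` (list: `chm`,
#'   `dem`, `cir` and `rgb` band lists) and `crowns`.
#' @export
simulate_landscape <- function(config, rasters = TRUE, crowns = rasters) {
  validate_landscape_config(config)
  set.seed(config$seed)
  s <- config$cell_size_m
  nr <- as.integer(round(config$extent_m[2] / s))
  nc <- as.integer(round(config$extent_m[1] / s))
  grid <- grid_spec(xmin = 0, ymax = config$extent_m[2], cell_size_m = s,
                    n_rows = nr, n_cols = nc, crs = "local")

  draw_field <- function() {
    if (config$field_type == "block")
      sim_blocks(nr, nc, s, config$block_size_m)
    else sim_grf(nr, nc, s, config$spatial_corr_range_m)
  }
  # shared structure couples BA and TPH (rho = 0.5); conifer share loads
  # weakly on the same structure (denser, better stocked cells skew conifer)
  z_common <- draw_field()
  z_ba <- sqrt(0.5) * z_common + sqrt(0.5) * draw_field()
  z_tph <- sqrt(0.5) * z_common + sqrt(0.5) * draw_field()
  z_con <- 0.3 * z_common + sqrt(1 - 0.09) * draw_field()

  pb <- lognormal_pars(config$ba_mean, max(config$ba_sd, 1e-12))
  pt_ <- lognormal_pars(config$tph_mean, max(config$tph_sd, 1e-12))
  ba_t <- if (config$ba_sd == 0) matrix(config$ba_mean, nr, nc) else
    exp(pb["mu"] + pb["sigma"] * z_ba)
  tph_t <- if (config$tph_sd == 0) matrix(config$tph_mean, nr, nc) else
    exp(pt_["mu"] + pt_["sigma"] * z_tph)
  pcon_t <- plogis(config$conifer_logit_mean +
                     config$conifer_logit_sd * z_con)

  stems <- draw_stems(grid, ba_t, tph_t, pcon_t, config)
  truth <- truth_from_stems(grid, stems)

  ras <- NULL
  crw <- NULL
  if (rasters) {
    ras <- list()
    ras$dem <- simulate_dem(config)
    ras$chm <- rasterize_chm(grid, stems, config)
    bands <- simulate_bands(grid, ba_t, pcon_t, config)
    ras$cir <- bands$cir
    ras$rgb <- bands$rgb
    if (crowns)
      crw <- segment_crowns(ras$chm, min_height_m = 2,
                            smoothing_sigma_m = max(0.5, config$chm_res_m),
                            min_area_m2 = 1)
  }
  targets <- data.frame(cell = seq_len(n_cells(grid)),
                        ba = as.vector(t(ba_t)),
                        tph = as.vector(t(tph_t)),
                        pcon = 100 * as.vector(t(pcon_t)))
  structure(list(config = config, grid = grid, stems = stems, truth = truth,
                 targets = targets, rasters = ras, crowns = crw),
            class = "landscape")
}

#' @exportS3Method base::print
print.landscape <- function(x, ...) {
  cat(sprintf("landscape: %.0f x %.0f m, %d cells, %d stems\n",
              x$config$extent_m[1], x$config$extent_m[2],
              n_cells(x$grid), nrow(x$stems)))
  invisible(x)
}

draw_stems <- function(grid, ba_t, tph_t, pcon_t, config) {
  cc <- cell_centers(grid)
  a_ha <- cell_area_ha(grid)
  s <- grid$cell_size_m
  # a cell cannot hold more >= min_dbh stems than its target BA allows;
  # capping the density keeps realized BA calibrated where QMD < min_dbh
  ba_floor <- pi * (config$min_dbh_cm / 200)^2
  tph_eff <- pmin(as.vector(t(tph_t)), as.vector(t(ba_t)) / ba_floor)
  lam <- pmin(tph_eff * a_ha, 5000)  # safety cap per cell
  n_i <- rpois(length(lam), lam)
  tot <- sum(n_i)
  if (tot == 0) {
    return(data.frame(x = numeric(0), y = numeric(0),
                      species = character(0), conifer = logical(0),
                      dbh_cm = numeric(0), height_m = numeric(0),
                      dead = logical(0), cell = integer(0)))
  }
  cell <- rep(cc$cell, n_i)
  ba_v <- rep(as.vector(t(ba_t)), n_i)
  tph_v <- rep(pmax(tph_eff, 1e-6), n_i)
  pcon <- rep(as.vector(t(pcon_t)), n_i)
  # quadratic mean diameter implied by the cell's BA and TPH targets;
  # diameters are min_dbh + gamma with the gamma mean m solved so that
  # E[DBH^2] = QMD^2, keeping realized BA calibrated to the target field
  qmd <- 200 * sqrt(pmax(ba_v / tph_v, 1e-8) / pi)
  cv <- 0.6                      # spread of the above-threshold excess
  d0 <- config$min_dbh_cm
  disc <- pmax(d0^2 - (1 + cv^2) * (d0^2 - qmd^2), 0)
  m <- pmax((sqrt(disc) - d0) / (1 + cv^2), 0.05)
  shape <- 1 / cv^2
  dbh <- d0 + rgamma(tot, shape = shape, scale = m / shape)
  conifer <- runif(tot) < pcon
  x0 <- rep(cc$x, n_i) - s / 2
  y0 <- rep(cc$y, n_i) - s / 2
  data.frame(x = x0 + runif(tot) * s, y = y0 + runif(tot) * s,
             species = ifelse(conifer, "CON", "HWD"),
             conifer = conifer, dbh_cm = dbh,
             height_m = tree_height(dbh, conifer),
             dead = runif(tot) < config$dead_fraction,
             cell = cell)
}

# Truth table recomputed from the realised stem map so downstream recovery
# tests compare against exactly what is on the ground.
truth_from_stems <- function(grid, stems) {
  a_ha <- cell_area_ha(grid)
  nidx <- n_cells(grid)
  ba_tree <- pi * (stems$dbh_cm / 200)^2
  ba <- sum_by(ba_tree, stems$cell, nidx) / a_ha
  cnt <- tabulate(stems$cell, nbins = nidx)
  ba_con <- sum_by(ba_tree * stems$conifer, stems$cell, nidx)
  hsum <- sum_by(stems$height_m, stems$cell, nidx)
  cc <- cell_centers(grid)
  data.frame(cell = cc$cell, x = cc$x, y = cc$y,
             ba = ba, tph = cnt / a_ha,
             pcon = ifelse(ba > 0, 100 * ba_con / (ba * a_ha), 0),
             height = ifelse(cnt > 0, hsum / cnt, 0))
}

simulate_dem <- function(config) {
  res <- config$dem_res_m
  nrp <- as.integer(round(config$extent_m[2] / res))
  ncp <- as.integer(round(config$extent_m[1] / res))
  xs <- (seq_len(ncp) - 0.5) * res
  ys <- config$extent_m[2] - (seq_len(nrp) - 0.5) * res
  L <- max(config$extent_m)
  th <- runif(2, 0, pi); ph <- runif(2, 0, 2 * pi)
  f1 <- outer(ys * sin(th[1]), xs * cos(th[1]), "+")
  f2 <- outer(ys * sin(th[2]), xs * cos(th[2]), "+")
  z <- 200 + 30 * sin(2 * pi * f1 / (L / 1.5) + ph[1]) +
    12 * sin(2 * pi * f2 / (L / 3) + ph[2])
  raster_layer(z, xmin = 0, ymax = config$extent_m[2], cell_size = res,
               crs = "local")
}

# CHM as the upper envelope of per-tree crown cones (paraboloid caps) on the
# CHM pixel grid, plus small truncated measurement noise.
rasterize_chm <- function(grid, stems, config) {
  res <- config$chm_res_m
  nrp <- as.integer(round(config$extent_m[2] / res))
  ncp <- as.integer(round(config$extent_m[1] / res))
  z <- matrix(0, nrp, ncp)
  if (nrow(stems) > 0) {
    sx <- stems$x; sy <- stems$y
    sr <- crown_radius(stems$dbh_cm); sh <- stems$height_m
    ord <- order(sh)  # tall trees rasterised last dominate ties
    for (i in ord) {
      r <- sr[i]
      h <- sh[i]
      cx <- sx[i]; cy <- sy[i]
      c0 <- max(1L, floor((cx - r) / res) + 1L)
      c1 <- min(ncp, floor((cx + r) / res) + 1L)
      r0 <- max(1L, floor((config$extent_m[2] - (cy + r)) / res) + 1L)
      r1 <- min(nrp, floor((config$extent_m[2] - (cy - r)) / res) + 1L)
      if (c0 > c1 || r0 > r1) next
      px <- (c0:c1 - 0.5) * res
      py <- config$extent_m[2] - (r0:r1 - 0.5) * res
      d2 <- outer((py - cy)^2, (px - cx)^2, "+")
      prof <- h * (1 - 0.4 * d2 / r^2)
      prof[d2 > r^2] <- 0
      blk <- z[r0:r1, c0:c1, drop = FALSE]
      z[r0:r1, c0:c1] <- pmax(blk, prof)
    }
  }
  # 15 cm vertical accuracy of the height surface
  z <- pmax(z + matrix(rnorm(nrp * ncp, 0, 0.15), nrp, ncp), 0)
  raster_layer(z, xmin = 0, ymax = config$extent_m[2], cell_size = res,
               crs = "local")
}

# Image bands: expectation is an affine function of target canopy cover
# (monotone in BA) and conifer share of the containing analysis cell, so the
# band/field relationship is exact when image_noise_sd = 0; pixel noise is
# the only within-cell texture.
simulate_bands <- function(grid, ba_t, pcon_t, config) {
  res <- config$img_res_m
  nrp <- as.integer(round(config$extent_m[2] / res))
  ncp <- as.integer(round(config$extent_m[1] / res))
  xs <- (seq_len(ncp) - 0.5) * res
  ys <- config$extent_m[2] - (seq_len(nrp) - 0.5) * res
  cells <- matrix(cell_of(grid, rep(xs, times = nrp), rep(ys, each = ncp)),
                  nrp, ncp, byrow = TRUE)
  ba <- matrix(as.vector(t(ba_t))[cells], nrp, ncp)
  pc <- matrix(as.vector(t(pcon_t))[cells], nrp, ncp)
  cover <- 1 - exp(-0.03 * ba)
  mk <- function(base, a_cov, a_con) {
    v <- base + a_cov * cover + a_con * pc
    if (config$image_noise_sd > 0)
      v <- v + matrix(rnorm(nrp * ncp, 0, config$image_noise_sd), nrp, ncp)
    raster_layer(pmin(pmax(v, 0.01), 1), xmin = 0,
                 ymax = config$extent_m[2], cell_size = res, crs = "local")
  }
  list(cir = list(nir = mk(0.30, 0.20, 0.15),
                  red = mk(0.28, -0.10, -0.06),
                  green = mk(0.22, -0.05, 0.00)),
       rgb = list(red = mk(0.28, -0.10, -0.06),
                  green = mk(0.22, -0.05, 0.00),
                  blue = mk(0.18, -0.04, 0.00)))
}

#' Limiting distance of a tree under a prism of given basal area factor
#'
#' A tree of diameter `dbh_cm` is tallied by a prism of basal area factor
#' `baf` iff its horizontal distance from plot centre is at most
#' `R = 50 * (dbh_cm / 100) / sqrt(baf)` metres, the closed form of
#' `baf = 2500 * (D / R)^2` with D and R in metres.
#'
#' @param dbh_cm diameter at breast height (cm), > 0.
#' @param baf basal area factor (m2/ha), > 0.
#' @return limiting distance in metres.
#' @examples
#' limiting_distance(40, 4.6)  # 9.325 m
#' @export
limiting_distance <- function(dbh_cm, baf) {
  if (any(dbh_cm <= 0) || any(baf <= 0))
    stop("limiting_distance: dbh_cm and baf must be positive", call. = FALSE)
  50 * (dbh_cm / 100) / sqrt(baf)
}

# 95% quantile of the radius of a circular bivariate normal is
# sigma * sqrt(qchisq(0.95, 2)) = 2.4477 sigma.
gps_sigma <- function(gps_error_95_m) gps_error_95_m / sqrt(qchisq(0.95, 2))

#' Simulate a variable-radius prism plot on a stem map
#'
#' Optionally jitters the nominal centre by circular bivariate normal GPS
#' error calibrated so 95% of realised centres fall within
#' `gps_error_95_m`, then tallies every stem with `dbh >= min_dbh_cm` whose
#' distance from the realised centre is at most its limiting distance.
#'
#' @param stems stem map data.frame (from [simulate_landscape()]).
#' @param location numeric `c(x, y)` nominal plot centre (m).
#' @param baf basal area factor of the prism (m2/ha).
#' @param min_dbh_cm measurement threshold (cm).
#' @param gps_error_95_m GPS error radius at 95% (m); 0 disables jitter.
#' @return object of class `prism_plot`: nominal and realised centre, baf,
#'   and the tally data.frame (species, conifer, dbh, height, dead, distance).
#' @export
simulate_prism_plot <- function(stems, location, baf = 4.6, min_dbh_cm = 14,
                                gps_error_95_m = 0) {
  center <- as.numeric(location)
  if (gps_error_95_m > 0)
    center <- center + rnorm(2, 0, gps_sigma(gps_error_95_m))
  tally <- stems[0, c("species", "conifer", "dbh_cm", "height_m", "dead")]
  tally$dist_m <- numeric(0)
  if (nrow(stems) > 0) {
    rmax <- limiting_distance(max(stems$dbh_cm), baf)
    near <- which(abs(stems$x - center[1]) <= rmax &
                    abs(stems$y - center[2]) <= rmax &
                    stems$dbh_cm >= min_dbh_cm)
    if (length(near) > 0) {
      d <- sqrt((stems$x[near] - center[1])^2 +
                  (stems$y[near] - center[2])^2)
      keep <- d <= limiting_distance(stems$dbh_cm[near], baf)
      tally <- stems[near[keep], c("species", "conifer", "dbh_cm",
                                   "height_m", "dead")]
      tally$dist_m <- d[keep]
      rownames(tally) <- NULL
    }
  }
  structure(list(nominal = as.numeric(location), center = center, baf = baf,
                 min_dbh_cm = min_dbh_cm, tally = tally),
            class = "prism_plot")
}

#' @exportS3Method base::print
print.prism_plot <- function(x, ...) {
  cat(sprintf("prism_plot: BAF %.1f, %d tallies, centre (%.1f, %.1f)\n",
              x$baf, nrow(x$tally), x$center[1], x$center[2]))
  invisible(x)
}

#' Simulate a batch of prism plots
#'
#' @param stems stem map.
#' @param locations data.frame with `x`, `y` nominal centres.
#' @param ... passed to [simulate_prism_plot()].
#' @param seed optional seed set before the batch (GPS jitter draws).
#' @return list of `prism_plot` objects.
#' @export
simulate_prism_plots <- function(stems, locations, ..., seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nrow(locations)), function(i)
    simulate_prism_plot(stems, c(locations$x[i], locations$y[i]), ...))
}
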