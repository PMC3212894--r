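#' Circular extraction of raster summaries around plot points
#'
#' Mean and standard deviation of each layer over the pixels whose centres
#' fall within `radius_m` of each plot point. Circles extending beyond a
#' layer flag the plot `partial` and summarize the covered part.
#'
#' @param layers named list of [raster_layer()]s.
#' @param points data.frame with `x`, `y`.
#' @param radius_m circle radius (m); must be at least one pixel of the
#'   coarsest layer.
#' @return data.frame: per layer `<name>_mean`, `<name>_sd`, plus `partial`.
#' @export
circular_extract <- function(layers, points, radius_m) {
  coarsest <- max(vapply(layers, function(r) r$cell_size, 0))
  if (radius_m < coarsest)
    stop("circular_extract: radius below one pixel of the coarsest layer",
         call. = FALSE)
  n <- nrow(points)
  out <- data.frame(row.names = seq_len(n))
  partial <- rep(FALSE, n)
  for (nm in names(layers)) {
    r <- layers[[nm]]
    ctr <- pixel_centers(r)
    mu <- numeric(n); sdv <- numeric(n)
    for (i in seq_len(n)) {
      x0 <- points$x[i]; y0 <- points$y[i]
      if (x0 - radius_m < r$xmin || x0 + radius_m > ras_xmax(r) ||
          y0 - radius_m < ras_ymin(r) || y0 + radius_m > r$ymax)
        partial[i] <- TRUE
      jx <- which(abs(ctr$x - x0) <= radius_m)
      iy <- which(abs(ctr$y - y0) <= radius_m)
      if (length(jx) == 0 || length(iy) == 0) {
        mu[i] <- NA; sdv[i] <- NA
        next
      }
      blk <- r$values[iy, jx, drop = FALSE]
      d2 <- outer((ctr$y[iy] - y0)^2, (ctr$x[jx] - x0)^2, "+")
      v <- blk[d2 <= radius_m^2]
      v <- v[!is.na(v)]
      mu[i] <- mean(v)
      sdv[i] <- if (length(v) > 1) sd(v) else 0
    }
    out[[paste0(nm, "_mean")]] <- mu
    out[[paste0(nm, "_sd")]] <- sdv
  }
  out$partial <- partial
  out
}

#' Exhaustive best-subset regression under BIC
#'
#' Enumerates every predictor subset up to `max_predictors` and returns the
#' one minimizing `BIC = n * ln(RSS / n) + (k + 1) * ln(n)` (k predictors
#' plus intercept). Enumeration is guarded at one million models.
#'
#' @param X candidate predictor matrix/data.frame.
#' @param y response vector.
#' @param max_predictors largest subset size (default 5).
#' @return list of class `best_subset`: `predictors`, `bic`, `r2`,
#'   `by_size` (best model per subset size).
#' @export
best_subset_bic <- function(X, y, max_predictors = 5) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  max_predictors <- min(max_predictors, p)
  n_models <- sum(choose(p, 0:max_predictors))
  if (n_models > 1e6)
    stop("best_subset_bic: ", format(n_models, big.mark = ","),
         " models exceed the enumeration guard; reduce max_predictors",
         call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  sst <- sum((y - mean(y))^2)
  bic_of <- function(rss, k) n * log(rss / n) + (k + 1) * log(n)

  best <- list(predictors = character(0), bic = bic_of(sst, 0),
               r2 = 0, k = 0L)
  by_size <- data.frame(k = 0L, bic = best$bic, r2 = 0,
                        predictors = "")
  for (k in seq_len(max_predictors)) {
    combs <- combn(p, k)
    kb <- Inf; kbest <- NULL; kr2 <- NA
    for (j in seq_len(ncol(combs))) {
      cols <- combs[, j]
      fit <- .lm.fit(cbind(1, X[, cols, drop = FALSE]), y)
      rss <- sum(fit$residuals^2)
      b <- bic_of(max(rss, 1e-300), k)
      if (b < kb) {
        kb <- b
        kbest <- cols
        kr2 <- 1 - rss / sst
      }
    }
    by_size <- rbind(by_size,
                     data.frame(k = k, bic = kb, r2 = kr2,
                                predictors = paste(colnames(X)[kbest],
                                                   collapse = ",")))
    if (kb < best$bic) {
      best <- list(predictors = colnames(X)[kbest], bic = kb, r2 = kr2,
                   k = as.integer(k))
    }
  }
  structure(c(best, list(by_size = by_size, n = n)), class = "best_subset")
}

#' @exportS3Method base::print
print.best_subset <- function(x, ...) {
  cat(sprintf("best_subset: k = %d, BIC = %.2f, R2 = %.3f\n",
              x$k, x$bic, x$r2))
  if (x$k > 0) cat(" ", paste(x$predictors, collapse = ", "), "\n")
  invisible(x)
}

#' Scan candidate grid-cell sizes by circular extraction and BIC search
#'
#' For each candidate cell area, remote-sensing summaries are extracted in a
#' circle of equal area (`r = sqrt(area / pi)`) around every plot, an
#' exhaustive lowest-BIC model search relates them to the plot response, and
#' the area whose best model attains the minimum BIC is selected (ties go to
#' the smaller area). Both BIC and R-squared are reported per size so the
#' variation-explained profile can be plotted.
#'
#' @param layers named list of [raster_layer()]s.
#' @param plots data.frame with `x`, `y` and the response column.
#' @param areas_ha candidate cell areas (ha), at least 3 unless overridden.
#' @param response name of the response column in `plots`.
#' @param max_predictors passed to [best_subset_bic()].
#' @param min_areas minimum number of candidate areas (contract default 3).
#' @return data.frame of class `gridsize_result` (one row per candidate:
#'   `area_ha`, `radius_m`, `bic`, `r2`, `k`, `predictors`), with the chosen
#'   optimum in attribute `optimum_ha`.
#' @export
scan_sizes <- function(layers, plots, areas_ha = c(0.02, 0.04, 0.06, 0.08,
                                                   0.10, 0.14, 0.20),
                       response = "y", max_predictors = 5, min_areas = 3) {
  if (length(areas_ha) < min_areas)
    stop("scan_sizes: need at least ", min_areas, " candidate areas",
         call. = FALSE)
  y <- plots[[response]]
  if (is.null(y)) stop("scan_sizes: response column '", response,
                       "' not found", call. = FALSE)
  rows <- lapply(sort(areas_ha), function(a) {
    radius <- sqrt(a * 1e4 / pi)
    feats <- tryCatch(
      circular_extract(layers, plots, radius),
      error = function(e) NULL)
    if (is.null(feats)) {
      warning("scan_sizes: area ", a, " ha skipped (radius below pixel)")
      return(NULL)
    }
    Xc <- feats[, setdiff(names(feats), "partial"), drop = FALSE]
    keep <- vapply(Xc, function(v) !anyNA(v) && sd(v) > 0, TRUE)
    Xc <- Xc[, keep, drop = FALSE]
    if (nrow(Xc) < ncol(Xc) + 2) {
      warning("scan_sizes: area ", a,
              " ha skipped (fewer plots than predictors + 2)")
      return(NULL)
    }
    bs <- best_subset_bic(Xc, y, max_predictors)
    data.frame(area_ha = a, radius_m = radius, bic = bs$bic, r2 = bs$r2,
               k = bs$k, predictors = paste(bs$predictors, collapse = ","))
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0)
    stop("scan_sizes: every candidate area was skipped", call. = FALSE)
  # minimum BIC; ties (within numerical noise) to the smaller area
  opt <- out$area_ha[order(out$bic + 1e-9 * out$area_ha)][1]
  attr(out, "optimum_ha") <- opt
  class(out) <- c("gridsize_result", "data.frame")
  out
}

#' Synthetic landscape with a known generative scale
#'
#' Builds the stated world for grid-size recovery experiments: a
#' piecewise-constant standard-normal field on square blocks of side
#' `block_m` (independent levels per block), a noisy observation layer on a
#' `px_m` pixel grid, and plots at the centres of randomly chosen interior
#' blocks whose response is the block value plus small measurement noise.
#' Because blocks are independent, the profitable extraction circle is the
#' largest one that stays inside the home block; the expected optimum area
#' is therefore near `pi * block_m^2 / 4` and can be computed exactly from
#' the geometry (see the methods vignette).
#'
#' @param extent_m square landscape side (m), a multiple of `block_m`.
#' @param px_m observation layer pixel size (m).
#' @param block_m block side (m), the generative correlation scale.
#' @param layer_noise_sd sd of iid pixel noise added to the layer.
#' @param response_noise_sd sd of plot measurement noise.
#' @param n_plots number of plots (capped at the interior block count).
#' @param margin_m edge margin excluded from plot placement (m).
#' @param seed RNG seed.
#' @return list: `layer` ([raster_layer()]), `field` (noise-free matrix),
#'   `plots` (data.frame `x`, `y`, `y_resp`), `block_m`.
#' @export
simulate_scale_landscape <- function(extent_m = 432, px_m = 2,
                                     block_m = 36, layer_noise_sd = 1.5,
                                     response_noise_sd = 0.1, n_plots = 40,
                                     margin_m = 40, seed = 1) {
  set.seed(seed)
  np <- as.integer(round(extent_m / px_m))
  f <- sim_blocks(np, np, px_m, block_m)
  layer <- raster_layer(f + matrix(rnorm(np * np, 0, layer_noise_sd),
                                   np, np),
                        cell_size = px_m, ymax = extent_m)
  nb <- floor(extent_m / block_m)
  cx <- (seq_len(nb) - 0.5) * block_m
  ctrs <- expand.grid(x = cx, y = cx)
  ok <- ctrs$x > margin_m & ctrs$x < extent_m - margin_m &
    ctrs$y > margin_m & ctrs$y < extent_m - margin_m
  ctrs <- ctrs[ok, ]
  pick <- ctrs[sample(nrow(ctrs), min(n_plots, nrow(ctrs))), ]
  i <- floor((extent_m - pick$y) / px_m) + 1
  j <- floor(pick$x / px_m) + 1
  pick$y_resp <- f[cbind(i, j)] + rnorm(nrow(pick), 0, response_noise_sd)
  rownames(pick) <- NULL
  list(layer = layer, field = f, plots = pick, block_m = block_m)
}

#' @exportS3Method base::print
print.gridsize_result <- function(x, ...) {
  cat("gridsize_result (optimum:", attr(x, "optimum_ha"), "ha)\n")
  print.data.frame(x)
  invisible(x)
}
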