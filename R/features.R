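#' Segment tree crowns from a canopy height model
#'
#' Watershed flooding of the Gaussian-smoothed CHM: seeds are 8-neighbour
#' local maxima at or above `min_height_m`, each above-threshold pixel joins
#' the crown it drains toward (flooding in descending height, deterministic
#' tie-break toward the lower pixel id). Crowns smaller than `min_area_m2`
#' are merged into the adjacent crown with the longest shared border, or
#' dropped when isolated.
#'
#' @param chm a [raster_layer()] canopy height model (m above ground).
#' @param min_height_m canopy threshold (m); below it is background.
#' @param smoothing_sigma_m Gaussian pre-smoothing sd (m).
#' @param min_area_m2 minimum crown area kept (m2).
#' @return object of class `crown_set`: `label` (a `raster_layer` of integer
#'   crown ids, 0 = background) and `crowns` (data.frame: id, n_px, area_m2,
#'   max_height_m, centroid_x, centroid_y).
#' @export
segment_crowns <- function(chm, min_height_m = 2, smoothing_sigma_m = 0.5,
                           min_area_m2 = 1) {
  stopifnot(inherits(chm, "raster_layer"))
  if (min_height_m <= 0 || smoothing_sigma_m <= 0 || min_area_m2 <= 0)
    stop("segment_crowns: parameters must be positive", call. = FALSE)
  v <- chm$values
  if (all(is.na(v))) {
    warning("segment_crowns: all-nodata CHM, returning no crowns")
    lab <- raster_layer(matrix(0L, nrow(v), ncol(v)), chm$xmin, chm$ymax,
                        chm$cell_size, chm$crs)
    return(structure(list(label = lab, crowns = empty_crown_table()),
                     class = "crown_set"))
  }
  sm <- smooth_gaussian(chm, smoothing_sigma_m)$values
  sm[is.na(v)] <- NA_real_
  lab <- watershed_labels_cpp(sm, min_height_m)
  # canopy is defined on the measured surface: smoothing steers seeds and
  # flooding only, it must not grow crowns past the real height threshold
  lab[is.na(v) | v < min_height_m] <- 0L
  lab <- merge_small_crowns(lab, min_area_m2 / chm$cell_size^2)
  crowns <- crown_table(lab, chm)
  structure(list(label = raster_layer(lab, chm$xmin, chm$ymax,
                                      chm$cell_size, chm$crs),
                 crowns = crowns),
            class = "crown_set")
}

#' @exportS3Method base::print
print.crown_set <- function(x, ...) {
  cat(sprintf("crown_set: %d crowns, %.1f m2 total area\n",
              nrow(x$crowns), sum(x$crowns$area_m2)))
  invisible(x)
}

empty_crown_table <- function() {
  data.frame(id = integer(0), n_px = integer(0), area_m2 = numeric(0),
             max_height_m = numeric(0), centroid_x = numeric(0),
             centroid_y = numeric(0))
}

merge_small_crowns <- function(lab, min_px) {
  repeat {
    sizes <- tabulate(lab[lab > 0])
    small <- which(sizes > 0 & sizes < min_px)
    if (length(small) == 0) break
    nr <- nrow(lab); nc <- ncol(lab)
    changed <- FALSE
    for (id in small) {
      px <- which(lab == id)
      r <- (px - 1) %% nr + 1
      c <- (px - 1) %/% nr + 1
      # neighbour labels over the 4-neighbourhood border
      nb <- integer(0)
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        rr <- r + d[1]; cc <- c + d[2]
        ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
        nb <- c(nb, lab[cbind(rr[ok], cc[ok])])
      }
      nb <- nb[nb > 0 & nb != id]
      lab[px] <- if (length(nb) > 0) {
        tt <- table(nb)
        as.integer(names(tt)[which.max(tt)])  # longest shared border
      } else 0L
      changed <- TRUE
    }
    if (!changed) break
  }
  # relabel consecutively
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) > 0) {
    map <- integer(max(ids))
    map[ids] <- seq_along(ids)
    pos <- lab > 0
    lab[pos] <- map[lab[pos]]
  }
  lab
}

crown_table <- function(lab, chm) {
  ids <- lab[lab > 0]
  if (length(ids) == 0) return(empty_crown_table())
  n <- max(ids)
  px <- which(lab > 0)
  f <- factor(lab[px], levels = seq_len(n))
  ctr <- pixel_centers(chm)
  r <- (px - 1) %% nrow(lab) + 1
  c <- (px - 1) %/% nrow(lab) + 1
  npx <- tabulate(ids, nbins = n)
  hmax <- vapply(split(chm$values[px], f), function(v)
    if (length(v)) max(v, na.rm = TRUE) else NA_real_, 0)
  data.frame(id = seq_len(n), n_px = npx,
             area_m2 = npx * chm$cell_size^2,
             max_height_m = as.numeric(hmax),
             centroid_x = sum_by(ctr$x[c], lab[px], n) / npx,
             centroid_y = sum_by(ctr$y[r], lab[px], n) / npx)
}

#' Export crowns to GeoJSON
#'
#' Writes one feature per crown. The geometry is the convex hull of the crown
#' pixel corners (an interchange approximation; all areas and metrics in the
#' package are computed from the exact pixel sets, carried in the
#' `area_m2` property).
#'
#' @param crown_set a [segment_crowns()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
crowns_to_geojson <- function(crown_set, path) {
  lab <- crown_set$label
  half <- lab$cell_size / 2
  ctr <- pixel_centers(lab)
  feats <- lapply(seq_len(nrow(crown_set$crowns)), function(i) {
    px <- which(lab$values == crown_set$crowns$id[i])
    r <- (px - 1) %% nrow(lab$values) + 1
    c <- (px - 1) %/% nrow(lab$values) + 1
    xs <- ctr$x[c]; ys <- ctr$y[r]
    pts <- cbind(c(xs - half, xs + half, xs + half, xs - half),
                 c(ys - half, ys - half, ys + half, ys + half))
    h <- grDevices::chull(pts)
    ring <- pts[c(h, h[1]), , drop = FALSE]
    list(type = "Feature",
         properties = list(id = crown_set$crowns$id[i],
                           area_m2 = crown_set$crowns$area_m2[i],
                           max_height_m = crown_set$crowns$max_height_m[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(j) ring[j, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}

#' Per-window image statistics
#'
#' Spatial-domain summaries of one band over one analysis cell: statistics of
#' all pixels, the average of the same statistics over the eight radial
#' profiles (centre to each corner and each edge midpoint), and histogram
#' quantile summaries. Entropy is Shannon entropy in bits over a 32-bin
#' equal-width histogram of the window's range (0 for a constant window).
#'
#' @param window numeric matrix of pixels, at least 4 x 4.
#' @param n_bins histogram bins for the entropy estimate.
#' @return named numeric vector (`px_*`, `pr_*`, `hist_*`).
#' @export
image_summaries <- function(window, n_bins = 32) {
  if (!is.matrix(window) || nrow(window) < 4 || ncol(window) < 4)
    stop("image_summaries: window must be at least 4 x 4 pixels",
         call. = FALSE)
  v <- as.numeric(window[!is.na(window)])
  px <- stat8(v, n_bins)
  names(px) <- paste0("px_", names(px))
  profs <- radial_profiles(window)
  pm <- rowMeans(vapply(profs, stat8, numeric(8), n_bins = n_bins))
  names(pm) <- paste0("pr_", names(pm))
  q <- quantile(v, c(0.1, 0.25, 0.75, 0.9), names = FALSE, type = 7)
  hist_ <- c(hist_p10 = q[1], hist_p25 = q[2], hist_p75 = q[3],
             hist_p90 = q[4], hist_iqr = q[3] - q[2],
             hist_range = max(v) - min(v))
  c(px, pm, hist_)
}

# mean, variance (population), median, skewness, excess kurtosis, entropy
# (bits), mean absolute deviation, median absolute deviation
stat8 <- function(v, n_bins = 32) {
  m <- mean(v)
  m2 <- mean((v - m)^2)
  skew <- if (m2 > 0) mean((v - m)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((v - m)^4) / m2^2 - 3 else 0
  med <- median(v)
  rng <- range(v)
  ent <- if (rng[2] > rng[1]) {
    br <- seq(rng[1], rng[2], length.out = n_bins + 1)
    cnt <- tabulate(pmin(findInterval(v, br, rightmost.closed = TRUE),
                         n_bins), nbins = n_bins)
    p <- cnt[cnt > 0] / length(v)
    -sum(p * log2(p))
  } else 0
  c(mean = m, var = m2, median = med, skew = skew, kurt = kurt,
    entropy = ent, mad = mean(abs(v - m)), medad = median(abs(v - med)))
}

radial_profiles <- function(window) {
  nr <- nrow(window); nc <- ncol(window)
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  targets <- list(c(1, 1), c(1, cc), c(1, nc), c(cr, nc),
                  c(nr, nc), c(nr, cc), c(nr, 1), c(cr, 1))
  lapply(targets, function(t) {
    n <- max(abs(t[1] - cr), abs(t[2] - cc)) + 1
    r <- round(seq(cr, t[1], length.out = n))
    c <- round(seq(cc, t[2], length.out = n))
    p <- window[cbind(r, c)]
    p[!is.na(p)]
  })
}

#' Summarize rasters, crowns and topography to the analysis grid
#'
#' Builds the per-cell feature table: topographic summaries (elevation,
#' slope, circular aspect, plane-departure), crown-segment metrics (count of
#' centroid-in-cell crowns, mean/variance of their maximum heights, crown
#' closure by pixel area, neighbourhood curvature, image bands fused to
#' crowns, IR/red ratio and NDVI) and spatial-domain image statistics per
#' band, with the CHM treated as a greyscale band. Means use all pixels whose
#' centre falls in the cell; variances are within-cell population variances.
#'
#' @param grid a [grid_spec()].
#' @param dem,chm [raster_layer()]s (optional, each adds its feature block).
#' @param cir,rgb named lists of band `raster_layer`s (CIR: nir/red/green;
#'   RGB: red/green/blue).
#' @param crowns a [segment_crowns()] result (optional).
#' @param intensity optional first-return intensity `raster_layer`.
#' @param min_window smallest pixel window accepted for image statistics.
#' @return data.frame of class `cell_features`, one row per grid cell, with
#'   a `partial` flag for cells not fully covered by every layer.
#' @export
summarize_cells <- function(grid, dem = NULL, chm = NULL, cir = NULL,
                            rgb = NULL, crowns = NULL, intensity = NULL,
                            min_window = 4) {
  out <- cell_centers(grid)
  partial <- rep(FALSE, nrow(out))

  check_crs <- function(r) {
    if (!identical(r$crs, grid$crs))
      stop("summarize_cells: CRS mismatch between layer ('", r$crs,
           "') and grid ('", grid$crs, "')", call. = FALSE)
  }

  if (!is.null(dem)) {
    check_crs(dem)
    idx <- raster_cell_index(dem, grid)
    partial <- partial | cell_coverage_flag(idx, dem, grid)
    out$elev_mean <- agg_mean(dem$values, idx, nrow(out))
    out$elev_var <- agg_popvar(dem$values, idx, nrow(out))
    ta <- terrain_slope_aspect(dem)
    out$slope_mean <- agg_mean(ta$slope$values, idx, nrow(out))
    out$slope_var <- agg_popvar(ta$slope$values, idx, nrow(out))
    asp <- circular_aspect_stats(ta$aspect$values, idx, nrow(out))
    out$aspect_mean <- asp$mean
    out$aspect_cvar <- asp$cvar
    out$plane_dep <- plane_departure(dem, grid)
  }

  if (!is.null(chm)) {
    check_crs(chm)
    idx <- raster_cell_index(chm, grid)
    partial <- partial | cell_coverage_flag(idx, chm, grid)
    out$chm_mean <- agg_mean(chm$values, idx, nrow(out))
    out$chm_var <- agg_popvar(chm$values, idx, nrow(out))
    out <- cbind(out, window_stats(chm, grid, "chm", min_window))
  }

  band_sets <- list(cir = cir, rgb = rgb)
  for (set in names(band_sets)) {
    bands <- band_sets[[set]]
    if (is.null(bands)) next
    for (bn in names(bands)) {
      b <- bands[[bn]]
      check_crs(b)
      idx <- raster_cell_index(b, grid)
      partial <- partial | cell_coverage_flag(idx, b, grid)
      pre <- paste0(set, "_", bn)
      out <- cbind(out, window_stats(b, grid, pre, min_window))
    }
    if (set == "cir" && all(c("nir", "red") %in% names(bands))) {
      nm <- paste0("cir_nir_px_mean"); rm_ <- paste0("cir_red_px_mean")
      out$ndvi <- (out[[nm]] - out[[rm_]]) / (out[[nm]] + out[[rm_]])
      out$ir_red_ratio <- out[[nm]] / out[[rm_]]
    }
  }

  if (!is.null(intensity)) {
    check_crs(intensity)
    idx <- raster_cell_index(intensity, grid)
    out$intensity_mean <- agg_mean(intensity$values, idx, nrow(out))
    out$intensity_var <- agg_popvar(intensity$values, idx, nrow(out))
  }

  if (!is.null(crowns)) {
    out <- cbind(out, crown_cell_metrics(crowns, grid, cir = cir, rgb = rgb))
    if (!is.null(out$chm_mean)) {
      # neighbourhood curvature: cell mean CHM height minus 8-neighbour mean
      m <- matrix(out$chm_mean, grid$n_rows, grid$n_cols, byrow = TRUE)
      out$crown_nln <- as.vector(t(m - neighbour_mean(m)))
    }
  }

  out$partial <- partial
  class(out) <- c("cell_features", "data.frame")
  out
}

# Sum v by integer group id into a length-n vector (0 where a group is
# empty). rowsum() drops empty groups and can reorder, so map explicitly.
sum_by <- function(v, idx, n) {
  ok <- !is.na(idx) & !is.na(v)
  s <- rowsum(v[ok], idx[ok], reorder = TRUE)
  out <- numeric(n)
  out[as.numeric(rownames(s))] <- s[, 1]
  out
}

count_by <- function(idx, n, na_v = NULL) {
  ok <- !is.na(idx)
  if (!is.null(na_v)) ok <- ok & !is.na(na_v)
  tabulate(idx[ok], nbins = n)
}

raster_cell_index <- function(r, grid) {
  ctr <- pixel_centers(r)
  cell_of(grid, rep(ctr$x, each = nrow(r$values)),
          rep(ctr$y, times = ncol(r$values)))
}

cell_coverage_flag <- function(idx, r, grid) {
  px_per_cell <- (grid$cell_size_m / r$cell_size)^2
  cnt <- tabulate(idx[!is.na(as.vector(r$values))], nbins = n_cells(grid))
  cnt < 0.999 * px_per_cell
}

agg_mean <- function(values, idx, n) {
  v <- as.vector(values)
  cnt <- count_by(idx, n, v)
  sum_by(v, idx, n) / ifelse(cnt > 0, cnt, NA)
}

agg_popvar <- function(values, idx, n) {
  v <- as.vector(values)
  cnt <- count_by(idx, n, v)
  m <- sum_by(v, idx, n) / ifelse(cnt > 0, cnt, NA)
  pmax(sum_by(v^2, idx, n) / ifelse(cnt > 0, cnt, NA) - m^2, 0)
}

circular_aspect_stats <- function(aspect_deg, idx, n) {
  v <- as.vector(aspect_deg) * pi / 180
  cnt <- count_by(idx, n, v)
  ss <- sum_by(sin(v), idx, n)
  cs <- sum_by(cos(v), idx, n)
  rbar <- sqrt(ss^2 + cs^2) / ifelse(cnt > 0, cnt, NA)
  mean_deg <- (atan2(ss, cs) * 180 / pi) %% 360
  mean_deg[cnt == 0] <- NA
  list(mean = mean_deg, cvar = ifelse(cnt > 0, 1 - rbar, NA))
}

# RMS departure of DEM pixels from the bilinear surface through the four
# cell-corner elevations (corners sampled from the nearest DEM pixel).
plane_departure <- function(dem, grid) {
  idx <- raster_cell_index(dem, grid)
  ctr <- pixel_centers(dem)
  px <- rep(ctr$x, each = nrow(dem$values))
  py <- rep(ctr$y, times = ncol(dem$values))
  v <- as.vector(dem$values)
  s <- grid$cell_size_m
  cc <- cell_centers(grid)
  corner_z <- function(x, y) {
    i <- pmin(pmax(round((dem$ymax - y) / dem$cell_size + 0.5), 1),
              nrow(dem$values))
    j <- pmin(pmax(round((x - dem$xmin) / dem$cell_size + 0.5), 1),
              ncol(dem$values))
    dem$values[cbind(i, j)]
  }
  z00 <- corner_z(cc$x - s / 2, cc$y + s / 2)  # NW
  z01 <- corner_z(cc$x + s / 2, cc$y + s / 2)  # NE
  z10 <- corner_z(cc$x - s / 2, cc$y - s / 2)  # SW
  z11 <- corner_z(cc$x + s / 2, cc$y - s / 2)  # SE
  ok <- !is.na(idx) & !is.na(v)
  id <- idx[ok]
  u <- (px[ok] - (cc$x[id] - s / 2)) / s          # 0..1 west->east
  w <- ((cc$y[id] + s / 2) - py[ok]) / s          # 0..1 north->south
  fit <- (1 - u) * (1 - w) * z00[id] + u * (1 - w) * z01[id] +
    (1 - u) * w * z10[id] + u * w * z11[id]
  n <- nrow(cc)
  cnt <- tabulate(id, nbins = n)
  msq <- sum_by((v[ok] - fit)^2, id, n) / ifelse(cnt > 0, cnt, NA)
  sqrt(msq)
}

window_stats <- function(r, grid, prefix, min_window) {
  idx <- raster_cell_index(r, grid)
  n <- n_cells(grid)
  nr <- nrow(r$values)
  res <- vector("list", n)
  ord <- split(seq_along(idx), factor(idx, levels = seq_len(n)))
  template <- NULL
  for (cell in seq_len(n)) {
    px <- ord[[cell]]
    if (length(px) == 0) {
      res[[cell]] <- NA
      next
    }
    rr <- (px - 1) %% nr + 1
    cc <- (px - 1) %/% nr + 1
    w <- matrix(NA_real_, max(rr) - min(rr) + 1, max(cc) - min(cc) + 1)
    w[cbind(rr - min(rr) + 1, cc - min(cc) + 1)] <- r$values[px]
    if (nrow(w) < min_window || ncol(w) < min_window)
      stop("summarize_cells: window for cell ", cell, " is smaller than ",
           min_window, "x", min_window, " pixels", call. = FALSE)
    st <- image_summaries(w)
    if (is.null(template)) template <- st
    res[[cell]] <- st
  }
  if (is.null(template)) template <- rep(NA_real_, 22)
  mat <- t(vapply(res, function(x)
    if (length(x) == length(template)) x else rep(NA_real_, length(template)),
    numeric(length(template))))
  colnames(mat) <- paste0(prefix, "_", names(template))
  as.data.frame(mat)
}

neighbour_mean <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(NA_real_, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  acc <- matrix(0, nr, nc)
  cnt <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    blk <- pad[2:(nr + 1) + dr, 2:(nc + 1) + dc, drop = FALSE]
    ok <- !is.na(blk)
    acc[ok] <- acc[ok] + blk[ok]
    cnt <- cnt + ok
  }
  acc / pmax(cnt, 1)
}

crown_cell_metrics <- function(crowns, grid, cir = NULL, rgb = NULL) {
  n <- n_cells(grid)
  tab <- crowns$crowns
  out <- data.frame(crown_pcount = integer(n),
                    crown_cell_height = numeric(n),
                    crown_height_var = numeric(n),
                    crown_closure = numeric(n),
                    crown_flag_empty = logical(n))
  lab <- crowns$label
  # closure: share of the cell's CHM-resolution pixels under any crown
  idx <- raster_cell_index(lab, grid)
  covered <- as.vector(lab$values) > 0
  cnt_all <- tabulate(idx, nbins = n)
  cnt_cov <- tabulate(idx[covered], nbins = n)
  out$crown_closure <- 100 * cnt_cov / ifelse(cnt_all > 0, cnt_all, NA)
  if (nrow(tab) > 0) {
    cid <- cell_of(grid, tab$centroid_x, tab$centroid_y)
    cnt <- count_by(cid, n)
    out$crown_pcount <- cnt
    hs <- sum_by(tab$max_height_m, cid, n)
    h2 <- sum_by(tab$max_height_m^2, cid, n)
    mh <- ifelse(cnt > 0, hs / cnt, 0)
    out$crown_cell_height <- mh
    out$crown_height_var <- ifelse(cnt > 0, pmax(h2 / cnt - mh^2, 0), 0)
    out$crown_flag_empty <- cnt == 0
    # fuse image bands to crowns: mean band value over crown pixels
    fuse <- function(band, nm) {
      bv <- sample_raster(band, crown_pixel_xy(lab))
      crown_ids <- as.vector(lab$values)[as.vector(lab$values) > 0]
      cm <- sum_by(bv, crown_ids, nrow(tab)) / tab$n_px
      per_cell_mean <- rep(NA_real_, n)
      per_cell_var <- rep(NA_real_, n)
      s1 <- sum_by(cm, cid, n)
      s2 <- sum_by(cm^2, cid, n)
      per_cell_mean[cnt > 0] <- (s1 / cnt)[cnt > 0]
      per_cell_var[cnt > 0] <- pmax(s2 / cnt - (s1 / cnt)^2, 0)[cnt > 0]
      df <- data.frame(per_cell_mean, per_cell_var)
      names(df) <- paste0("crown_", nm, c("_mean", "_var"))
      df
    }
    if (!is.null(cir) && !is.null(cir$nir))
      out <- cbind(out, fuse(cir$nir, "nir"))
    if (!is.null(rgb))
      for (bn in names(rgb)) out <- cbind(out, fuse(rgb[[bn]], bn))
    if (!is.null(out$crown_nir_mean) && !is.null(out$crown_red_mean)) {
      out$crown_ir_red_ratio <- out$crown_nir_mean / out$crown_red_mean
      out$crown_ndvi <- (out$crown_nir_mean - out$crown_red_mean) /
        (out$crown_nir_mean + out$crown_red_mean)
    }
  } else {
    out$crown_flag_empty <- TRUE
  }
  out
}

crown_pixel_xy <- function(lab) {
  px <- which(lab$values > 0)
  ctr <- pixel_centers(lab)
  r <- (px - 1) %% nrow(lab$values) + 1
  c <- (px - 1) %/% nrow(lab$values) + 1
  cbind(ctr$x[c], ctr$y[r])
}

sample_raster <- function(r, xy) {
  i <- pmin(pmax(ceiling((r$ymax - xy[, 2]) / r$cell_size), 1),
            nrow(r$values))
  j <- pmin(pmax(ceiling((xy[, 1] - r$xmin) / r$cell_size), 1),
            ncol(r$values))
  r$values[cbind(i, j)]
}
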