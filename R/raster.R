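#' Georeferenced numeric grid
#'
#' A minimal raster container: a numeric matrix with rows running north to
#' south and columns west to east, an origin at the north-west corner, a cell
#' size in metres and a CRS tag. `NA` encodes nodata.
#'
#' @param values numeric matrix, rows north to south.
#' @param xmin x coordinate of the west edge (m).
#' @param ymax y coordinate of the north edge (m).
#' @param cell_size pixel edge length (m).
#' @param crs free-text coordinate reference tag; layers are only combined
#'   when tags match.
#' @return an object of class `raster_layer`.
#' @export
raster_layer <- function(values, xmin = 0, ymax = nrow(values) * cell_size,
                         cell_size = 1, crs = "local") {
  stopifnot(is.matrix(values), cell_size > 0)
  structure(list(values = values, xmin = xmin, ymax = ymax,
                 cell_size = cell_size, crs = crs),
            class = "raster_layer")
}

#' @exportS3Method base::print
print.raster_layer <- function(x, ...) {
  cat(sprintf("raster_layer: %d x %d px, %.3g m cells, crs '%s'\n",
              nrow(x$values), ncol(x$values), x$cell_size, x$crs))
  cat(sprintf("  extent x [%.1f, %.1f]  y [%.1f, %.1f]\n",
              x$xmin, x$xmin + ncol(x$values) * x$cell_size,
              x$ymax - nrow(x$values) * x$cell_size, x$ymax))
  invisible(x)
}

ras_xmax <- function(r) r$xmin + ncol(r$values) * r$cell_size
ras_ymin <- function(r) r$ymax - nrow(r$values) * r$cell_size

#' Pixel-centre coordinates of a raster
#'
#' @param r a [raster_layer()].
#' @return list with vectors `x` (per column) and `y` (per row).
#' @export
pixel_centers <- function(r) {
  list(x = r$xmin + (seq_len(ncol(r$values)) - 0.5) * r$cell_size,
       y = r$ymax - (seq_len(nrow(r$values)) - 0.5) * r$cell_size)
}

#' Write / read a raster as Esri ASCII grid
#'
#' Plain-text interchange format readable by every GIS; used here because no
#' binary GeoTIFF driver is assumed on the host.
#'
#' @param r a [raster_layer()].
#' @param path file path (conventionally `.asc`).
#' @param nodata value written for `NA` cells.
#' @return `write_asc` returns `path` invisibly; `read_asc` a `raster_layer`.
#' @export
write_asc <- function(r, path, nodata = -9999) {
  v <- r$values
  v[is.na(v)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(v)),
           sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.10g", r$xmin),
           sprintf("yllcorner %.10g", ras_ymin(r)),
           sprintf("cellsize %.10g", r$cell_size),
           sprintf("NODATA_value %.10g", nodata))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(v, trim = TRUE, digits = 8), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_asc
#' @param crs CRS tag to attach on read (the format does not carry one).
#' @export
read_asc <- function(path, crs = "local") {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(tolower(hdr), "\\s+")
  h <- setNames(as.numeric(vapply(kv, `[`, "", 2)),
                vapply(kv, `[`, "", 1))
  v <- as.matrix(read.table(path, skip = 6))
  dimnames(v) <- NULL
  v[v == h[["nodata_value"]]] <- NA_real_
  raster_layer(v, xmin = h[["xllcorner"]],
               ymax = h[["yllcorner"]] + h[["nrows"]] * h[["cellsize"]],
               cell_size = h[["cellsize"]], crs = crs)
}

#' Analysis grid specification
#'
#' Cells are half-open squares `[x, x+s) x (y-s, y]`, identified row-major
#' from the north-west corner, matching the convention used for all cell
#' summaries.
#'
#' @param xmin,ymax north-west corner of the grid (m).
#' @param cell_size_m cell edge (m); 20 m gives the 400 m2 analysis cell.
#' @param n_rows,n_cols grid dimensions.
#' @param crs CRS tag.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(xmin = 0, ymax, cell_size_m = 20, n_rows, n_cols,
                      crs = "local") {
  stopifnot(cell_size_m > 0, n_rows >= 1, n_cols >= 1)
  structure(list(xmin = xmin, ymax = ymax, cell_size_m = cell_size_m,
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 crs = crs),
            class = "grid_spec")
}

#' @exportS3Method base::print
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells of %.3g m (%.3g ha each), crs '%s'\n",
              x$n_rows, x$n_cols, x$cell_size_m,
              x$cell_size_m^2 / 1e4, x$crs))
  invisible(x)
}

n_cells <- function(grid) grid$n_rows * grid$n_cols

cell_area_ha <- function(grid) grid$cell_size_m^2 / 1e4

#' Map coordinates to grid cell ids
#'
#' @param grid a [grid_spec()].
#' @param x,y coordinates (m).
#' @return integer cell ids (row-major from NW); `NA` outside the grid.
#' @export
cell_of <- function(grid, x, y) {
  s <- grid$cell_size_m
  col <- floor((x - grid$xmin) / s) + 1
  row <- floor((grid$ymax - y) / s) + 1
  bad <- col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows
  id <- (row - 1) * grid$n_cols + col
  id[bad] <- NA_integer_
  as.integer(id)
}

#' Cell-centre coordinates for every cell of a grid
#'
#' @param grid a [grid_spec()].
#' @return data.frame with `cell`, `row`, `col`, `x`, `y`.
#' @export
cell_centers <- function(grid) {
  s <- grid$cell_size_m
  row <- rep(seq_len(grid$n_rows), each = grid$n_cols)
  col <- rep(seq_len(grid$n_cols), times = grid$n_rows)
  data.frame(cell = seq_len(n_cells(grid)), row = row, col = col,
             x = grid$xmin + (col - 0.5) * s,
             y = grid$ymax - (row - 0.5) * s)
}

#' Gaussian smoothing of a raster
#'
#' Separable Gaussian convolution with edge renormalisation (kernel weights
#' falling outside the raster are dropped and the remainder rescaled).
#'
#' @param r a [raster_layer()] or plain matrix.
#' @param sigma_m kernel standard deviation in metres (matrix input: pixels).
#' @return same type as the input.
#' @export
smooth_gaussian <- function(r, sigma_m) {
  is_ras <- inherits(r, "raster_layer")
  m <- if (is_ras) r$values else r
  sigma_px <- if (is_ras) sigma_m / r$cell_size else sigma_m
  if (sigma_px <= 0) return(r)
  sm <- gauss_1d_mat(nrow(m), sigma_px) %*% m %*%
    t(gauss_1d_mat(ncol(m), sigma_px))
  if (is_ras) raster_layer(sm, r$xmin, r$ymax, r$cell_size, r$crs) else sm
}

gauss_1d_mat <- function(n, sigma_px) {
  half <- max(1L, ceiling(3 * sigma_px))
  d <- outer(seq_len(n), seq_len(n), "-")
  k <- exp(-0.5 * (d / sigma_px)^2)
  k[abs(d) > half] <- 0
  k / rowSums(k)
}

#' Slope and aspect from a DEM (Horn's method)
#'
#' Central finite differences on the 3x3 neighbourhood. Aspect is degrees
#' clockwise from north; flat pixels get `NA` aspect.
#'
#' @param dem a [raster_layer()] of elevations (m).
#' @return list of two `raster_layer`s: `slope` (degrees) and `aspect`.
#' @export
terrain_slope_aspect <- function(dem) {
  z <- dem$values
  s <- dem$cell_size
  nr <- nrow(z); nc <- ncol(z)
  pad <- z[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  sh <- function(dr, dc) pad[seq_len(nr) + 1 + dr, seq_len(nc) + 1 + dc]
  # Horn weights
  dzdx <- ((sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
             (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))) / (8 * s)
  dzdy <- ((sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
             (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))) / (8 * s)
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  aspect <- (atan2(dzdx, -dzdy) * 180 / pi) %% 360  # downslope dir from north
  aspect[dzdx == 0 & dzdy == 0] <- NA_real_
  list(slope = raster_layer(slope, dem$xmin, dem$ymax, s, dem$crs),
       aspect = raster_layer(aspect, dem$xmin, dem$ymax, s, dem$crs))
}
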