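#' Volume proxy: basal area times canopy height
#'
#' @param pred_ba per-cell basal area (m2/ha), non-negative.
#' @param mean_chm_height per-cell mean canopy height (m), non-negative.
#' @return per-cell proxy `ba * height`.
#' @export
volume_proxy <- function(pred_ba, mean_chm_height) {
  if (length(pred_ba) != length(mean_chm_height))
    stop("volume_proxy: input lengths differ", call. = FALSE)
  if (any(pred_ba < 0, na.rm = TRUE) || any(mean_chm_height < 0,
                                            na.rm = TRUE))
    stop("volume_proxy: inputs must be non-negative", call. = FALSE)
  pred_ba * mean_chm_height
}

#' Optimal one-dimensional binning by dynamic programming
#'
#' Partitions values into `k` contiguous bins of the sorted order minimizing
#' the total within-bin sum of squared deviations, solved exactly by
#' Fisher's O(k n^2) dynamic program on the sorted unique values with
#' multiplicities. Exactness is the point: the DP doubles as its own oracle
#' against brute-force enumeration at small n.
#'
#' @param values numeric vector (n >= k).
#' @param k number of bins.
#' @return list of class `optimal_bins`: `assignment` (bin index 1..k per
#'   input value, 1 = lowest), `breaks` (k-1 interior cut points, midpoints
#'   between adjacent unique values), `sse` (optimal total within-bin SSE),
#'   `k`.
#' @export
optimal_bin <- function(values, k) {
  v <- as.numeric(values)
  if (anyNA(v)) stop("optimal_bin: missing values", call. = FALSE)
  if (k < 1) stop("optimal_bin: k must be >= 1", call. = FALSE)
  if (length(v) < k)
    stop("optimal_bin: need at least k values", call. = FALSE)
  u <- sort(unique(v))
  if (k > length(u))
    stop("optimal_bin: k exceeds the number of distinct values",
         call. = FALSE)
  w <- as.numeric(table(factor(v, levels = u)))
  dp <- fisher_dp_cpp(u, w, as.integer(k))
  starts <- dp$starts
  breaks <- if (k > 1)
    (u[starts[-1]] + u[starts[-1] - 1]) / 2 else numeric(0)
  assignment <- findInterval(v, breaks) + 1L
  structure(list(assignment = assignment, breaks = breaks, sse = dp$sse,
                 k = as.integer(k)),
            class = "optimal_bins")
}

#' @exportS3Method base::print
print.optimal_bins <- function(x, ...) {
  cat(sprintf("optimal_bins: k = %d, SSE = %.4g\n", x$k, x$sse))
  invisible(x)
}

#' Non-forest mask
#'
#' Cells strictly below both the crown-closure and canopy-height thresholds
#' are labelled non-forest (stratum 0) and excluded from binning; a cell at
#' either threshold counts as forest.
#'
#' @param cells a [summarize_cells()] table (needs `crown_closure` and
#'   `chm_mean`).
#' @param closure_threshold_pct crown closure threshold (%).
#' @param height_threshold_m mean canopy height threshold (m).
#' @return logical vector, `TRUE` for non-forest cells.
#' @export
nonforest_mask <- function(cells, closure_threshold_pct = 10,
                           height_threshold_m = 2) {
  if (is.null(cells$crown_closure) || is.null(cells$chm_mean))
    stop("nonforest_mask: crown_closure and chm_mean required",
         call. = FALSE)
  closure <- ifelse(is.na(cells$crown_closure), 0, cells$crown_closure)
  height <- ifelse(is.na(cells$chm_mean), 0, cells$chm_mean)
  closure < closure_threshold_pct & height < height_threshold_m
}

#' Stratify cells by optimal binning of the volume proxy
#'
#' Bins forested cells into `k` strata by [optimal_bin()] on the proxy,
#' labels strata 1..k in ascending proxy mean (0 = non-forest), then
#' enforces the minimum stratum area with [enforce_min_area()].
#'
#' @param proxy per-cell volume proxy.
#' @param nonforest logical per-cell non-forest flag (stratum 0).
#' @param k number of forested strata requested.
#' @param cell_area_ha area of one cell (ha).
#' @param attributes data.frame with per-cell `ba`, `height`, `tph`, `pcon`
#'   used for the attribute-nearness merge.
#' @param min_area_ha minimum stratum area (default 4.05 ha = 10 acres).
#' @return list of class `stratum_assignment`: `labels` (0 = non-forest),
#'   `table` (per-stratum summary, see [stratum_table()]), `k_final`.
#' @export
stratify_cells <- function(proxy, nonforest = rep(FALSE, length(proxy)),
                           k, cell_area_ha, attributes = NULL,
                           min_area_ha = 4.05) {
  labels <- integer(length(proxy))
  fidx <- which(!nonforest)
  if (length(fidx) < k)
    stop("stratify_cells: fewer forested cells than strata", call. = FALSE)
  ob <- optimal_bin(proxy[fidx], k)
  labels[fidx] <- ob$assignment
  if (!is.null(attributes))
    labels <- enforce_min_area(labels, proxy, attributes, cell_area_ha,
                               min_area_ha)
  tab <- stratum_table(labels, proxy, cell_area_ha, attributes)
  structure(list(labels = labels, table = tab,
                 k_final = length(unique(labels[labels > 0]))),
            class = "stratum_assignment")
}

#' Per-stratum summary table
#'
#' @param labels per-cell stratum labels (0 = non-forest).
#' @param proxy per-cell volume proxy.
#' @param cell_area_ha cell area (ha).
#' @param attributes optional data.frame (`ba`, `height`, `tph`, `pcon`).
#' @return data.frame with one row per stratum: cell count, area (ha), proxy
#'   mean/variance and attribute means.
#' @export
stratum_table <- function(labels, proxy, cell_area_ha, attributes = NULL) {
  lev <- sort(unique(labels))
  out <- data.frame(stratum = lev,
                    n_cells = as.integer(table(factor(labels,
                                                      levels = lev))))
  out$area_ha <- out$n_cells * cell_area_ha
  f <- factor(labels, levels = lev)
  out$proxy_mean <- as.numeric(tapply(proxy, f, mean))
  out$proxy_var <- as.numeric(tapply(proxy, f, function(v)
    if (length(v) > 1) var(v) else 0))
  if (!is.null(attributes))
    for (a in intersect(c("ba", "height", "tph", "pcon"), names(attributes)))
      out[[paste0("mean_", a)]] <-
        as.numeric(tapply(attributes[[a]], f, mean))
  out
}

#' Enforce the minimum stratum area by attribute-nearness cell swaps
#'
#' Undersized forested strata (area below `min_area_ha`) are dissolved
#' smallest-first: each of their cells moves to whichever stratum adjacent in
#' proxy rank is nearest in standardized attribute space (z-scored Euclidean
#' distance over basal area, height, stems/ha and conifer share between the
#' cell and the candidate stratum mean). Labels are renumbered to
#' consecutive ascending proxy rank after every dissolution and areas
#' re-checked; the stratum count never increases.
#'
#' @param labels per-cell labels (0 = non-forest).
#' @param proxy per-cell volume proxy (defines stratum rank order).
#' @param attributes data.frame with `ba`, `height`, `tph`, `pcon` per cell.
#' @param cell_area_ha cell area (ha).
#' @param min_area_ha minimum area per forested stratum (default 4.05).
#' @return relabelled integer vector.
#' @export
enforce_min_area <- function(labels, proxy, attributes, cell_area_ha,
                             min_area_ha = 4.05) {
  need <- c("ba", "height", "tph", "pcon")
  if (!all(need %in% names(attributes)))
    stop("enforce_min_area: attributes must have ",
         paste(need, collapse = ", "), call. = FALSE)
  A <- as.matrix(attributes[, need])
  forest <- labels > 0
  sds <- apply(A[forest, , drop = FALSE], 2, sd)
  sds[sds == 0 | is.na(sds)] <- 1
  Z <- sweep(A, 2, sds, "/")  # landscape-wide standardization

  relabel <- function(lab) {
    lev <- sort(unique(lab[lab > 0]))
    if (length(lev) == 0) return(lab)
    mns <- vapply(lev, function(l) mean(proxy[lab == l]), 0)
    ord <- lev[order(mns)]
    map <- integer(max(lev))
    map[ord] <- seq_along(ord)
    pos <- lab > 0
    lab[pos] <- map[lab[pos]]
    lab
  }
  labels <- relabel(labels)

  repeat {
    lev <- sort(unique(labels[labels > 0]))
    areas <- vapply(lev, function(l)
      sum(labels == l) * cell_area_ha, 0)
    under <- lev[areas < min_area_ha]
    if (length(under) == 0) break
    if (length(lev) == 1) {
      warning("enforce_min_area: total forested area below the minimum; ",
              "returning a single forested stratum")
      break
    }
    tgt <- under[which.min(areas[match(under, lev)])]  # smallest first
    pos <- match(tgt, lev)
    cand <- c(if (pos > 1) lev[pos - 1], if (pos < length(lev)) lev[pos + 1])
    cmeans <- lapply(cand, function(l)
      colMeans(Z[labels == l, , drop = FALSE]))
    for (i in which(labels == tgt)) {
      d <- vapply(cmeans, function(m) sqrt(sum((Z[i, ] - m)^2)), 0)
      labels[i] <- cand[which.min(d)]
    }
    labels <- relabel(labels)
  }
  labels
}
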