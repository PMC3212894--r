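#' Reduce a feature block to leading principal components
#'
#' Principal components of the correlation matrix by default (features are on
#' wildly different scales); a covariance mode (`scale = FALSE`) exists for
#' raw-variance analyses and tests. Constant columns are dropped with a
#' warning before the decomposition. Each loading vector is oriented so its
#' largest-magnitude element is positive, making scores reproducible across
#' platforms.
#'
#' @param features numeric matrix or data.frame, cells x variables, no
#'   missing values.
#' @param k number of retained components (default 8).
#' @param scale use the correlation matrix (`TRUE`, default) or covariance.
#' @param name label for the set (e.g. "CIR", "RGB", "LI").
#' @param kaiser if `TRUE`, retain by the Kaiser criterion (eigenvalue > 1 in
#'   correlation mode) instead of a fixed `k`.
#' @return object of class `component_set`: `loadings` (p x k, orthonormal),
#'   `var_explained` (all components, non-increasing, sums to 1), `scores`
#'   (n x k), plus centring/scaling vectors.
#' @export
pca_reduce <- function(features, k = 8, scale = TRUE, name = "SET",
                       kaiser = FALSE) {
  X <- as.matrix(features)
  if (anyNA(X)) stop("pca_reduce: missing values in features", call. = FALSE)
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    warning("pca_reduce: dropping constant column(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  if (ncol(X) < 1) stop("pca_reduce: no non-constant columns", call. = FALSE)
  pc <- stats::prcomp(X, center = TRUE, scale. = scale)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  if (kaiser) {
    thr <- if (scale) 1 else mean(pc$sdev^2)
    k <- max(1L, sum(pc$sdev^2 > thr))
  }
  k <- min(k, ncol(pc$rotation))
  # deterministic sign: largest |loading| positive
  flip <- apply(pc$rotation[, seq_len(k), drop = FALSE], 2, function(l)
    sign(l[which.max(abs(l))]))
  loadings <- sweep(pc$rotation[, seq_len(k), drop = FALSE], 2, flip, "*")
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, "*")
  colnames(scores) <- colnames(loadings) <- paste0(name, seq_len(k))
  structure(list(name = name, loadings = loadings, var_explained = ve,
                 scores = scores, k = k, center = pc$center,
                 scale = if (scale) pc$scale else NULL),
            class = "component_set")
}

#' @exportS3Method base::print
print.component_set <- function(x, ...) {
  cat(sprintf("component_set '%s': %d components, %.1f%% variance\n",
              x$name, x$k, 100 * sum(x$var_explained[seq_len(x$k)])))
  invisible(x)
}

#' Cross-correlation of two component score sets
#'
#' Pearson correlations between every pair of columns, with two-sided
#' significance flags, used to diagnose overlap between image sets that share
#' bands.
#'
#' @param a,b score matrices with equal row counts (n >= 3).
#' @param alpha significance level for the flags.
#' @return list: `r` (|A| x |B| correlation matrix), `p` (p-values),
#'   `flag` (logical, `p < alpha`).
#' @export
cross_correlation <- function(a, b, alpha = 0.05) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b))
    stop("cross_correlation: row counts differ", call. = FALSE)
  n <- nrow(a)
  if (n < 3) stop("cross_correlation: need at least 3 rows", call. = FALSE)
  r <- cor(a, b)
  r_ <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tstat <- r_ * sqrt((n - 2) / (1 - r_^2))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  list(r = r, p = p, flag = p < alpha)
}
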