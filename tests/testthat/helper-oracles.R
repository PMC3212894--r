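# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute force, enumeration and direct textbook
# formulas only.

# small, cheap landscape for structural tests
tiny_config <- function(..., seed = 11) {
  landscape_config(extent_m = 160, cell_size_m = 20, tph_mean = 800,
                   tph_sd = 400, chm_res_m = 1, dem_res_m = 2,
                   img_res_m = 2, seed = seed, ...)
}

# brute-force variable-radius tally: scan every stem against the rule
oracle_tally <- function(stems, center, baf, min_dbh) {
  d <- sqrt((stems$x - center[1])^2 + (stems$y - center[2])^2)
  lim <- 50 * (stems$dbh_cm / 100) / sqrt(baf)
  which(stems$dbh_cm >= min_dbh & d <= lim)
}

# exhaustive optimal binning: all placements of k-1 boundaries between
# sorted values
oracle_bin_sse <- function(values, k) {
  v <- sort(values)
  n <- length(v)
  sse_seg <- function(seg) sum((seg - mean(seg))^2)
  if (k == 1) return(sse_seg(v))
  cuts <- combn(n - 1, k - 1)
  best <- Inf
  for (j in seq_len(ncol(cuts))) {
    b <- c(0, cuts[, j], n)
    # boundaries must fall between distinct values to define a valid binning
    # of ties; enumerating positions covers every assignment of sorted data
    s <- sum(vapply(seq_len(k), function(m)
      sse_seg(v[(b[m] + 1):b[m + 1]]), 0))
    if (s < best) best <- s
  }
  best
}

# stratified-mean variance of an integer allocation (finite pop ignored,
# matching the estimator's formula)
oracle_strat_var <- function(W, S, n) sum(W^2 * S^2 / n)

# all integer allocations of total over H strata with n_h in [lo, N]
oracle_all_allocations <- function(H, total, N, lo = 0) {
  if (H == 1) {
    if (total >= lo && total <= N[1]) return(matrix(total, 1, 1))
    return(matrix(numeric(0), 0, 1))
  }
  out <- list()
  for (a in max(lo, total - sum(N[-1])):min(N[1], total)) {
    rest <- oracle_all_allocations(H - 1, total - a, N[-1], lo)
    if (nrow(rest) > 0) out[[length(out) + 1]] <- cbind(a, rest)
  }
  if (length(out) == 0) return(matrix(numeric(0), 0, H))
  do.call(rbind, out)
}

# empirical semivariogram and fitted exponential practical range
oracle_variogram_range <- function(x, y, v, max_lag, n_bins = 12) {
  idx <- seq_along(v)
  pr <- expand.grid(i = idx, j = idx)
  pr <- pr[pr$i < pr$j, ]
  d <- sqrt((x[pr$i] - x[pr$j])^2 + (y[pr$i] - y[pr$j])^2)
  g <- 0.5 * (v[pr$i] - v[pr$j])^2
  keep <- d <= max_lag
  d <- d[keep]; g <- g[keep]
  br <- seq(0, max_lag, length.out = n_bins + 1)
  bin <- cut(d, br, labels = FALSE)
  dm <- tapply(d, bin, mean)
  gm <- tapply(g, bin, mean)
  ok <- !is.na(dm)
  dm <- dm[ok]; gm <- gm[ok]
  sill0 <- max(gm)
  obj <- function(p) {
    fit <- p[1] * (1 - exp(-3 * dm / p[2]))
    sum((fit - gm)^2)
  }
  optim(c(sill0, max_lag / 2), obj, method = "L-BFGS-B",
        lower = c(1e-6, 1), upper = c(10 * sill0, 10 * max_lag))$par[2]
}

# direct per-statistic recomputation for image windows
oracle_stats <- function(v) {
  m <- mean(v)
  m2 <- mean((v - m)^2)
  list(mean = m, var = m2, median = median(v),
       skew = if (m2 > 0) mean((v - m)^3) / m2^1.5 else 0,
       kurt = if (m2 > 0) mean((v - m)^4) / m2^2 - 3 else 0,
       mad = mean(abs(v - m)),
       medad = median(abs(v - median(v))))
}

# forward stepwise under BIC, for the exhaustive-search dominance check
oracle_forward_bic <- function(X, y, max_k) {
  X <- as.matrix(X)
  n <- length(y)
  bic_of <- function(rss, k) n * log(rss / n) + (k + 1) * log(n)
  sel <- integer(0)
  best <- bic_of(sum((y - mean(y))^2), 0)
  repeat {
    if (length(sel) >= max_k) break
    cand <- setdiff(seq_len(ncol(X)), sel)
    scores <- vapply(cand, function(j) {
      f <- .lm.fit(cbind(1, X[, c(sel, j), drop = FALSE]), y)
      bic_of(sum(f$residuals^2), length(sel) + 1)
    }, 0)
    if (min(scores) >= best) break
    sel <- c(sel, cand[which.min(scores)])
    best <- min(scores)
  }
  best
}
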