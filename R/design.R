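#' Neyman (optimal) sample allocation across strata
#'
#' Allocates `total_n` plots in proportion to `N_h * S_h` (or
#' `N_h * S_h / sqrt(c_h)` with per-stratum costs). Integerization is by
#' greedy marginal variance reduction, which attains the exact integer
#' optimum of the stratified-mean variance `sum(W_h^2 S_h^2 / n_h)` because
#' the objective is separable and convex; the `n_h <= N_h` cap is respected
#' during the greedy pass. The per-stratum floor (so stratum variances stay
#' estimable) is applied last and can push the realized total above the
#' request; the result carries a `floored` flag per stratum.
#'
#' @param N per-stratum population cell counts (> 0).
#' @param S per-stratum standard deviations (>= 0), measured or model-based.
#' @param total_n requested total number of plots.
#' @param floor minimum plots for any sampled stratum (default 2).
#' @param costs optional per-stratum unit costs (optimal allocation).
#' @return data.frame of class `allocation_plan`: `stratum`, `N`, `S`, `n`,
#'   `floored`.
#' @export
neyman_allocate <- function(N, S, total_n, floor = 2, costs = NULL) {
  if (any(N <= 0)) stop("neyman_allocate: all N must be > 0", call. = FALSE)
  if (any(S < 0)) stop("neyman_allocate: S must be >= 0", call. = FALSE)
  H <- length(N)
  if (length(S) != H) stop("neyman_allocate: N and S lengths differ",
                           call. = FALSE)
  w <- N * S
  if (!is.null(costs)) {
    if (any(costs <= 0)) stop("neyman_allocate: costs must be > 0",
                              call. = FALSE)
    w <- w / sqrt(costs)
  }
  sampled <- w > 0
  n_floor_req <- sum(pmin(floor, N[sampled]))
  if (total_n < n_floor_req)
    stop("neyman_allocate: total_n below the floors; need at least ",
         n_floor_req, call. = FALSE)
  # Greedy marginal-gain integerization: the objective sum W_h^2 S_h^2 / n_h
  # is separable and convex in n_h, so assigning one plot at a time to the
  # stratum with the largest variance reduction (per unit cost) attains the
  # exact integer optimum. First plots (n_h: 0 -> 1) have infinite gain and
  # are ordered by N_h * S_h.
  cost <- if (is.null(costs)) rep(1, H) else costs
  n <- integer(H)
  gain <- function(h) {
    if (n[h] >= N[h]) return(-Inf)          # stratum exhausted
    if (n[h] == 0) return(Inf)
    w[h]^2 * (1 / n[h] - 1 / (n[h] + 1)) / cost[h]
  }
  if (any(sampled)) {
    for (it in seq_len(total_n)) {
      g <- rep(-Inf, H)
      for (h in which(sampled)) g[h] <- gain(h)
      if (all(g == -Inf)) break               # every stratum exhausted
      first <- g == Inf
      h <- if (any(first)) {
        cand <- which(first)
        cand[order(-w[cand], cand)][1]        # first plots by N_h S_h rank
      } else which.max(g)
      n[h] <- n[h] + 1L
    }
  }
  floored <- sampled & n < pmin(floor, N)
  n[floored] <- pmin(floor, N)[floored]
  structure(data.frame(stratum = seq_len(H), N = N, S = S, n = n,
                       floored = floored),
            class = c("allocation_plan", "data.frame"))
}

#' Model-based stratum standard deviation
#'
#' For strata with too few plots to estimate variability from the field
#' sample, the per-cell model predictions within the stratum stand in:
#' `S_h` is their sample standard deviation.
#'
#' @param predictions back-transformed per-cell model predictions within one
#'   stratum (length >= 2).
#' @return the standard deviation estimate.
#' @export
model_variance <- function(predictions) {
  if (length(predictions) < 2)
    stop("model_variance: need at least 2 cells", call. = FALSE)
  sd(predictions)
}

#' Randomly place plots within strata
#'
#' Simple random sample of cells without replacement within each stratum
#' (each cell receives at most one plot); the plot goes at the cell centre.
#'
#' @param labels per-cell stratum labels (0 = non-forest, never sampled).
#' @param grid the [grid_spec()] the labels index.
#' @param n_h named or ordered vector of plots per forested stratum, in
#'   ascending stratum label order.
#' @param seed RNG seed for reproducible placement.
#' @return data.frame: `stratum`, `cell`, `x`, `y`.
#' @export
place_plots <- function(labels, grid, n_h, seed = 1) {
  lev <- sort(unique(labels[labels > 0]))
  if (length(n_h) != length(lev))
    stop("place_plots: n_h must have one entry per forested stratum",
         call. = FALSE)
  set.seed(seed)
  cc <- cell_centers(grid)
  out <- lapply(seq_along(lev), function(i) {
    cells <- which(labels == lev[i])
    if (n_h[i] > length(cells))
      stop("place_plots: n_h exceeds the stratum cell count", call. = FALSE)
    if (n_h[i] == 0) return(NULL)
    pick <- cells[sample.int(length(cells), n_h[i])]
    data.frame(stratum = lev[i], cell = pick, x = cc$x[pick],
               y = cc$y[pick])
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
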