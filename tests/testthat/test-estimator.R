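fake_plot <- function(dbh, conifer = TRUE, dead = FALSE, baf = 4.6,
                      height = 30) {
  n <- length(dbh)
  conifer <- rep_len(conifer, n)
  structure(list(nominal = c(0, 0), center = c(0, 0), baf = baf,
                 min_dbh_cm = 14,
                 tally = data.frame(species = ifelse(conifer, "CON", "HWD"),
                                    conifer = conifer,
                                    dbh_cm = dbh,
                                    height_m = rep_len(height, n),
                                    dead = rep_len(dead, n),
                                    dist_m = rep_len(1, n))),
            class = "prism_plot")
}

test_that("prism expansion arithmetic is exact", {
  p <- fake_plot(rep(30, 10))
  s <- plot_statistics(p)
  expect_identical(s$ba, 4.6 * 10)
  one <- fake_plot(25)
  s1 <- plot_statistics(one)
  expect_equal(s1$tph, 4.6 / (pi * 0.125^2), tolerance = 1e-9)
  expect_equal(s1$tph, 93.71, tolerance = 1e-2)
  expect_equal(s1$pcon, 100)
  mixed <- fake_plot(c(20, 30, 40), conifer = c(TRUE, TRUE, FALSE))
  expect_equal(plot_statistics(mixed)$pcon, 100 * 2 / 3)
  empty <- fake_plot(numeric(0))
  expect_equal(plot_statistics(empty)$ba, 0)
  bad <- fake_plot(c(10, -1))
  expect_error(plot_statistics(bad), "tree\\(s\\) 2")
})

test_that("dead trees enter carbon only when asked", {
  p <- fake_plot(c(30, 30), dead = c(FALSE, TRUE))
  c_live <- plot_statistics(p)$carbon_mg
  c_all <- plot_statistics(p, include_dead_carbon = TRUE)$carbon_mg
  expect_equal(c_all, 2 * c_live)
})

test_that("post-stratified estimate reproduces the textbook example", {
  # W=(0.6,0.4), ybar=(10,20), s2=(4,9), n=(4,3)
  y1 <- 10 + c(-1, -1, 1, 1) * sqrt(3)      # mean 10, var 4
  y2 <- c(17, 20, 23)                        # mean 20, var 9
  strata <- data.frame(stratum = 1:2, area_ha = c(60, 40))
  es <- poststratified_estimate(c(y1, y2), rep(1:2, c(4, 3)), strata)
  expect_equal(es$mean, 14, tolerance = 1e-9)
  expect_equal(es$variance, 0.84, tolerance = 1e-9)
  expect_equal(es$se, 0.9165, tolerance = 1e-4)
  expect_equal(es$half_width, qt(0.95, es$df) * es$se, tolerance = 1e-12)
})

test_that("single stratum reduces to SRS and zero variance gives 0 accuracy", {
  set.seed(50)
  y <- rnorm(12, 50, 5)
  es <- poststratified_estimate(y, rep(1L, 12),
                                data.frame(stratum = 1, area_ha = 10))
  expect_equal(es$mean, mean(y))
  expect_equal(es$se, sd(y) / sqrt(12))
  expect_equal(es$df, 11)
  cst <- poststratified_estimate(rep(7, 8), rep(1L, 8),
                                 data.frame(stratum = 1, area_ha = 10))
  expect_equal(cst$accuracy_pct, 0)
})

test_that("accuracy is scale invariant and unknown strata are rejected", {
  set.seed(51)
  y <- rlnorm(20, 3, 0.4)
  lab <- rep(1:2, each = 10)
  strata <- data.frame(stratum = 1:2, area_ha = c(30, 70))
  a1 <- poststratified_estimate(y, lab, strata)$accuracy_pct
  a2 <- poststratified_estimate(1000 * y, lab, strata)$accuracy_pct
  expect_equal(a1, a2, tolerance = 1e-12)
  expect_error(poststratified_estimate(y, rep(3, 20), strata), "absent")
})

test_that("strata with < 2 plots are folded into a rank neighbour", {
  y <- c(10, 12, 99, 30, 31, 29)
  lab <- c(1L, 1L, 2L, 3L, 3L, 3L)
  strata <- data.frame(stratum = 1:3, area_ha = c(10, 1, 10))
  es <- poststratified_estimate(y, lab, strata)
  expect_equal(length(es$folds), 1L)
  expect_equal(nrow(es$strata), 2L)
  expect_equal(sum(es$strata$W), 1)
})

test_that("tree lists conserve basal area and average over plots", {
  p1 <- fake_plot(c(21, 23, 40), conifer = c(TRUE, TRUE, FALSE))
  tl1 <- strata_tree_list(list(p1))
  expect_equal(nrow(tl1), 2L)  # classes 20 (2 conifers) and 40 (1 hwd)
  expect_equal(sum(tl1$ba), plot_statistics(p1)$ba)
  tl2 <- strata_tree_list(list(p1, p1))
  expect_equal(tl2$tph, tl1$tph)
  set.seed(52)
  plots <- lapply(1:6, function(i) fake_plot(runif(rpois(1, 8) + 1, 15, 90),
                                             conifer = runif(1) < 0.5))
  tl <- strata_tree_list(plots)
  mean_ba <- mean(vapply(plots, function(p) plot_statistics(p)$ba, 0))
  expect_equal(sum(tl$ba), mean_ba, tolerance = 1e-6)
})

test_that("stratified design beats SRS on heterogeneous populations, not homogeneous", {
  set.seed(53)
  n <- 1500
  lab <- optimal_bin(sort(rlnorm(n, 3.5, 0.5)), 5)$assignment
  values <- sort(rlnorm(n, 3.5, 0.5))  # strongly stratified by construction
  res <- compare_designs(values, lab, n_total = 50, replicates = 100,
                         seed = 2)
  expect_gt(mean(res$acc_strat < res$acc_srs), 0.95)
  # homogeneous population: paired difference CI covers 0
  hom <- rnorm(n, 50, 5)
  labh <- sample(1:5, n, replace = TRUE)
  resh <- compare_designs(hom, labh, n_total = 50, replicates = 100,
                          seed = 3)
  d <- resh$acc_strat - resh$acc_srs
  ci <- mean(d) + c(-2, 2) * sd(d) / sqrt(length(d))
  expect_true(ci[1] <= 0 && 0 <= ci[2] || abs(mean(d)) < 0.5)
  expect_warning(compare_designs(hom, labh, 30, replicates = 10, seed = 1),
                 "30 replicates")
})
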