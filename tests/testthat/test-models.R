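make_lasso_case <- function(seed, n = 200, p_decoy = 20, beta = 2,
                            noise = 0.05) {
  set.seed(seed)
  X <- matrix(rnorm(n * (p_decoy + 1)), n,
              dimnames = list(NULL, c("x1", paste0("d", seq_len(p_decoy)))))
  y <- beta * X[, "x1"] + rnorm(n, 0, noise)
  list(X = X, y = y)
}

test_that("lasso screen recovers a known support", {
  hits <- vapply(1:20, function(s) {
    cs <- make_lasso_case(s)
    sel <- lasso_screen(cs$X, cs$y, folds = 10, seed = s)$selected
    identical(sel, "x1")
  }, TRUE)
  expect_gte(sum(hits), 18)
})

test_that("lasso screen handles null signal and duplicated columns", {
  set.seed(99)
  X <- matrix(rnorm(100 * 10), 100)
  y <- rnorm(100)
  out <- suppressWarnings(lasso_screen(X, y, seed = 1))
  expect_lte(length(out$selected), 2)  # essentially nothing real to find
  # duplicated signal column: at most one of the pair enters
  set.seed(7)
  X2 <- matrix(rnorm(200 * 5), 200,
               dimnames = list(NULL, paste0("x", 1:5)))
  X2 <- cbind(X2, twin = X2[, "x1"])
  y2 <- 3 * X2[, "x1"] + rnorm(200, 0, 0.5)
  sel <- lasso_screen(X2, y2, seed = 2)$selected
  expect_lte(sum(c("x1", "twin") %in% sel), 1)
  expect_error(lasso_screen(X2[1:5, ], y2[1:5], folds = 10), "folds")
})

test_that("log model refit is exact on noiseless data", {
  set.seed(4)
  x <- runif(50, 0, 4)
  y <- exp(1 + 0.5 * x)
  m <- fit_model(cbind(x = x), y, transform = "log")
  expect_equal(unname(m$coefficients), c(1, 0.5), tolerance = 1e-10)
  expect_equal(m$r2, 1, tolerance = 1e-12)
  expect_equal(m$offset, 0)  # no zeros, no offset
  # with zeros the default offset engages
  y0 <- c(y, 0)
  m0 <- fit_model(cbind(x = c(x, 0)), y0, transform = "log")
  expect_equal(m0$offset, 1)
})

test_that("logistic model basics", {
  m <- fit_model(matrix(0, 40, 0), rep(0.5, 40), transform = "logit")
  expect_equal(unname(m$coefficients[1]), 0, tolerance = 1e-9)
  expect_error(fit_model(cbind(x = 1:5), c(0.1, 0.5, 2, 0.3, 0.4),
                         transform = "logit"), "0,1")
})

test_that("singular designs are rejected with the offending columns named", {
  x <- rnorm(30)
  expect_error(fit_model(cbind(a = x, b = 2 * x), exp(x), "log"),
               "collinear")
})

test_that("post-lasso OLS residuals are orthogonal to selected predictors", {
  cs <- make_lasso_case(3, noise = 1)
  sel <- lasso_screen(cs$X, cs$y, seed = 3)$selected
  m <- fit_model(cs$X[, sel, drop = FALSE], exp(cs$y), transform = "log")
  eta <- m$coefficients[1] +
    drop(cs$X[, sel, drop = FALSE] %*% m$coefficients[-1])
  res <- cs$y - eta
  for (v in sel) expect_lt(abs(sum(res * cs$X[, v])), 1e-8)
})

test_that("post-Lasso coefficient CIs achieve nominal coverage (n = 500)", {
  cover <- vapply(1:200, function(s) {
    set.seed(s + 1000)
    n <- 500
    X <- matrix(rnorm(n * 6), n,
                dimnames = list(NULL, c("x1", paste0("d", 1:5))))
    y <- exp(3 + 0.4 * X[, "x1"] + rnorm(n, 0, 0.4))
    sel <- suppressWarnings(
      lasso_screen(X, log(y), folds = 5, seed = s)$selected)
    if (!"x1" %in% sel) return(NA)
    m <- fit_model(X[, sel, drop = FALSE], y, transform = "log")
    est <- m$coefficients[["x1"]]
    se <- m$coef_se[["x1"]]
    tq <- qt(0.975, m$df_residual)
    est - tq * se <= 0.4 && 0.4 <= est + tq * se
  }, NA)
  expect_gte(mean(cover, na.rm = TRUE), 0.93)
  expect_lt(mean(is.na(cover)), 0.05)  # the signal is essentially always kept
})

test_that("predictions back-transform with the documented bias correction", {
  cells <- data.frame(x = c(0, 1, 2))
  m <- list(transform = "log", predictors = character(0),
            coefficients = c(`(Intercept)` = 3), sigma = 0.5, offset = 0,
            bias_correct = FALSE)
  class(m) <- "stand_model"
  expect_equal(predict_cells(m, cells), rep(exp(3), 3))
  expect_equal(predict_cells(m, cells, bias_correct = TRUE) /
                 predict_cells(m, cells),
               rep(exp(0.5^2 / 2), 3))
  m$predictors <- "zz"
  expect_error(predict_cells(m, cells), "zz")
})

test_that("bias correction reduces back-transform bias on average", {
  diffs <- vapply(1:100, function(s) {
    set.seed(s)
    n <- 150
    x <- rnorm(n)
    y <- exp(2 + 0.5 * x + rnorm(n, 0, 0.6))
    m <- fit_model(cbind(x = x), y, transform = "log")
    newx <- data.frame(x = rnorm(500))
    truth_mean <- mean(exp(2 + 0.5 * newx$x) * exp(0.6^2 / 2))
    with_c <- mean(predict_cells(m, newx, bias_correct = TRUE))
    without <- mean(predict_cells(m, newx, bias_correct = FALSE))
    abs(with_c - truth_mean) - abs(without - truth_mean)
  }, 0)
  expect_lt(mean(diffs), 0)  # corrected is closer on average
})

test_that("prediction is monotone in a positively-signed predictor", {
  set.seed(11)
  x <- runif(100, 0, 2)
  y <- exp(1 + 0.8 * x + rnorm(100, 0, 0.1))
  m <- fit_model(cbind(x = x), y, transform = "log")
  grid <- data.frame(x = seq(0, 2, length.out = 50))
  p <- predict_cells(m, grid)
  expect_true(all(diff(p) > 0))
})

test_that("a normality check is computed and reported", {
  set.seed(12)
  m <- fit_model(cbind(x = rnorm(200)), exp(rnorm(200) + 2), "log")
  expect_true(is.finite(m$normality$statistic))
  expect_true(m$normality$p_value >= 0 && m$normality$p_value <= 1)
})

test_that("sample efficiency is 2(1 - sqrt(R2))", {
  expect_equal(round(100 * sample_efficiency(0.635), 1), 40.6)
  expect_equal(round(100 * sample_efficiency(0.568), 1), 49.3)
  expect_equal(sample_efficiency(1), 0)
  expect_equal(sample_efficiency(0), 2)
  expect_error(sample_efficiency(1.2), "0,1")
  expect_error(sample_efficiency(-0.1), "0,1")
})
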