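#' Lasso variable screen
#'
#' Selects predictors by the Lasso with the penalty chosen by k-fold
#' cross-validation (pure minimum rule, seeded fold assignment). Predictors
#' are centred and scaled internally so no single variable swamps the
#' others; the selected set is the nonzero-coefficient set at the
#' cross-validated penalty.
#'
#' @param X candidate predictor matrix or data.frame (no missing values).
#' @param y transformed response vector.
#' @param folds number of cross-validation folds (default 10).
#' @param seed seed controlling the fold assignment.
#' @return list of class `lasso_screen`: `selected` (character vector,
#'   possibly empty), `lambda`, and the `cv.glmnet` fit.
#' @export
lasso_screen <- function(X, y, folds = 10, seed = 1) {
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(y))
    stop("lasso_screen: missing values", call. = FALSE)
  n <- nrow(X)
  if (n < folds || folds < 2)
    stop("lasso_screen: need n >= folds >= 2", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  set.seed(seed)
  foldid <- sample(rep(seq_len(folds), length.out = n))
  cv <- glmnet::cv.glmnet(X, y, foldid = foldid, standardize = TRUE)
  beta <- coef(cv, s = "lambda.min")[-1, 1]
  selected <- names(beta)[beta != 0]
  if (length(selected) == 0)
    warning("lasso_screen: empty selection (intercept-only model)")
  structure(list(selected = selected, lambda = cv$lambda.min, cv = cv),
            class = "lasso_screen")
}

#' @exportS3Method base::print
print.lasso_screen <- function(x, ...) {
  cat(sprintf("lasso_screen: %d predictors at lambda = %.4g\n",
              length(x$selected), x$lambda))
  if (length(x$selected)) cat(" ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Fit a stand model on the selected predictors
#'
#' Post-selection refit: natural-log responses (basal area, stems per
#' hectare) are fitted by ordinary least squares on the transformed scale;
#' proportion responses (conifer basal-area share) by quasi-binomial
#' maximum likelihood through the logit link, optionally weighted by tally
#' counts. Zero responses under the log transform are handled by a
#' configurable additive offset (default 1 unit, applied only when zeros are
#' present and removed again after back-transformation).
#'
#' @param X matrix/data.frame of the selected predictors (may have 0 columns
#'   for an intercept-only model).
#' @param y raw response: positive-or-zero values for `"log"`, proportions in
#'   \\[0,1\\] for `"logit"`.
#' @param transform `"log"` or `"logit"`.
#' @param offset additive offset before the log transform; `NULL` picks 0
#'   when all `y > 0`, else 1.
#' @param weights optional per-observation weights (tally counts for the
#'   logistic model).
#' @param bias_correct default state of the log-normal back-transform
#'   correction `exp(sigma^2/2)` used by [predict_cells()].
#' @return object of class `stand_model` carrying coefficients, the fit MSE
#'   and R-squared on the transformed scale, the R-squared recomputed on the
#'   natural scale, the residual sd, and a Pearson chi-square normality test
#'   of the residuals.
#' @export
fit_model <- function(X, y, transform = c("log", "logit"), offset = NULL,
                      weights = NULL, bias_correct = TRUE) {
  transform <- match.arg(transform)
  X <- as.matrix(X)
  if (nrow(X) == 0 || length(y) != nrow(X))
    stop("fit_model: X and y sizes disagree", call. = FALSE)
  if (ncol(X) > 0) {
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    qx <- qr(cbind(1, X))
    if (qx$rank < ncol(X) + 1) {
      bad <- colnames(X)[qx$pivot[seq(qx$rank + 1, ncol(X) + 1)] - 1]
      stop("fit_model: singular design; collinear columns: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  dat <- data.frame(X, check.names = FALSE)

  if (transform == "log") {
    if (is.null(offset)) offset <- if (all(y > 0)) 0 else 1
    if (any(y + offset <= 0))
      stop("fit_model: nonpositive response after offset", call. = FALSE)
    yt <- log(y + offset)
    fml <- if (ncol(X) > 0) yt ~ . else yt ~ 1
    fit <- lm(fml, data = dat)
    res <- resid(fit)
    p <- length(coef(fit))
    sigma <- sqrt(sum(res^2) / max(length(yt) - p, 1))
    sst <- sum((yt - mean(yt))^2)
    r2 <- if (sst > 0) 1 - sum(res^2) / sst else 1
    pred_nat <- pmax(exp(fitted(fit)) - offset, 0)
    sst_nat <- sum((y - mean(y))^2)
    r2_nat <- if (sst_nat > 0) 1 - sum((y - pred_nat)^2) / sst_nat else 1
    norm_test <- pearson_normality(res)
    # noiseless fits are a legitimate degenerate case; silence lm's warning
    sm <- suppressWarnings(summary(fit))
    mod <- list(transform = "log", predictors = colnames(X),
                coefficients = coef(fit),
                coef_se = sm$coefficients[, "Std. Error"],
                df_residual = fit$df.residual, sigma = sigma,
                mse = mean(res^2), r2 = r2, r2_natural = r2_nat,
                offset = offset, bias_correct = bias_correct,
                n = length(y), normality = norm_test)
  } else {
    if (any(y < 0 | y > 1))
      stop("fit_model: logit response must lie in [0,1]", call. = FALSE)
    w <- if (is.null(weights)) rep(1, length(y)) else weights
    fml <- if (ncol(X) > 0) y ~ . else y ~ 1
    fit <- suppressWarnings(glm(fml, data = cbind(dat, y = y),
                                family = quasibinomial(), weights = w))
    eta <- predict(fit, type = "link")
    res <- y - fitted(fit)
    r2 <- if (var(y) > 0) cor(fitted(fit), y)^2 else 1
    mod <- list(transform = "logit", predictors = colnames(X),
                coefficients = coef(fit),
                coef_se = summary(fit)$coefficients[, "Std. Error"],
                df_residual = fit$df.residual, sigma = sqrt(mean(res^2)),
                mse = mean(res^2), r2 = r2, r2_natural = r2,
                offset = 0, bias_correct = FALSE,
                n = length(y), normality = NULL)
  }
  class(mod) <- "stand_model"
  mod
}

#' @exportS3Method base::print
print.stand_model <- function(x, ...) {
  cat(sprintf("stand_model (%s): %d predictors, R2 = %.3f, MSE = %.4f\n",
              x$transform, length(x$predictors), x$r2, x$mse))
  print(round(x$coefficients, 5))
  invisible(x)
}

# Pearson chi-square test of normality: residuals partitioned into classes
# equiprobable under the fitted normal; statistic ~ chi-square with
# (classes - 3) df after fitting mean and sd.
pearson_normality <- function(res, n_classes = NULL) {
  n <- length(res)
  if (is.null(n_classes)) n_classes <- max(4, ceiling(2 * n^0.4))
  br <- qnorm(seq(0, 1, length.out = n_classes + 1), mean(res),
              sd(res))
  br[1] <- -Inf; br[n_classes + 1] <- Inf
  obs <- tabulate(findInterval(res, br, rightmost.closed = TRUE),
                  nbins = n_classes)
  expd <- n / n_classes
  stat <- sum((obs - expd)^2 / expd)
  df <- max(n_classes - 3, 1)
  list(statistic = stat, df = df, p_value = pchisq(stat, df,
                                                   lower.tail = FALSE))
}

#' Predict stand attributes for every grid cell
#'
#' Applies a [fit_model()] result to a cell feature table. Log models are
#' back-transformed with `exp()` with an optional multiplicative bias
#' correction `exp(sigma^2 / 2)`; logistic predictions are returned on the
#' 0--100 percent scale.
#'
#' @param model a `stand_model`.
#' @param cells data.frame containing every selected predictor column.
#' @param bias_correct override the model's stored flag.
#' @return numeric vector of per-cell predictions in natural units.
#' @export
predict_cells <- function(model, cells, bias_correct = model$bias_correct) {
  miss <- setdiff(model$predictors, names(cells))
  if (length(miss) > 0)
    stop("predict_cells: missing predictor column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  X <- if (length(model$predictors) > 0)
    as.matrix(cells[, model$predictors, drop = FALSE]) else
      matrix(0, nrow(cells), 0)
  eta <- model$coefficients[1] + drop(X %*% model$coefficients[-1])
  if (model$transform == "log") {
    out <- exp(eta)
    if (isTRUE(bias_correct)) out <- out * exp(model$sigma^2 / 2)
    pmax(out - model$offset, 0)
  } else {
    100 * plogis(eta)
  }
}

#' Relative sampling efficiency of a correlated auxiliary variable
#'
#' For a model with coefficient of determination `r_squared`, the ratio of
#' correlated to uncorrelated plots needed for equal precision is
#' `2 * (1 - rho)` with `rho = sqrt(r_squared)`.
#'
#' @param r_squared coefficient of determination in \\[0,1\\].
#' @return efficiency as a fraction (multiply by 100 for percent).
#' @examples
#' sample_efficiency(0.635)  # 0.406: 40.6% of the plots suffice
#' @export
sample_efficiency <- function(r_squared) {
  if (any(!is.finite(r_squared)) || any(r_squared < 0 | r_squared > 1))
    stop("sample_efficiency: r_squared must lie in [0,1]", call. = FALSE)
  2 * (1 - sqrt(r_squared))
}
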