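# QSAR validation-metric suite: RMSE, the two R-squared forms, leave-one-
# out cross-validation, external predictivity, the Roy rm2 family and
# Lin's concordance correlation coefficient. All sums of squares are raw
# sums (no n vs n-1 convention), exactly as the defining formulas state.

check_lengths <- function(a, b) {
  if (length(a) != length(b)) stop("input vectors must have equal length")
}

#' Root-mean-square error
#'
#' @param obs,pred numeric vectors of equal length.
#' @return RMSE (same units as the inputs).
#' @export
rmse <- function(obs, pred) {
  check_lengths(obs, pred)
  if (!length(obs)) stop("need at least one observation")
  sqrt(mean((obs - pred)^2))
}

#' Squared Pearson correlation (trendline R2)
#'
#' The R-squared of the least-squares trendline between two variables --
#' the form used for observed-vs-predicted scatter correlations. Distinct
#' from [r2_fit()], the 1 - SSres/SStot form: on a panel whose predictions
#' are systematically offset the trendline form can be large while the
#' residual form is negative.
#'
#' @param x,y numeric vectors (n >= 3, both non-constant).
#' @return Squared correlation in \[0, 1\].
#' @export
pearson_r2 <- function(x, y) {
  check_lengths(x, y)
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("inputs must not be constant")
  }
  stats::cor(x, y)^2
}

#' Coefficient of determination (residual form)
#'
#' \eqn{1 - \sum(obs - pred)^2 / \sum(obs - \bar{obs})^2}; may be negative
#' when predictions are worse than the mean.
#'
#' @param obs,pred numeric vectors.
#' @return R2 (unitless, at most 1).
#' @export
r2_fit <- function(obs, pred) {
  check_lengths(obs, pred)
  if (length(obs) < 2L) stop("need at least 2 pairs")
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) stop("obs must not be constant")
  1 - sum((obs - pred)^2) / sst
}

#' Leave-one-out cross-validation
#'
#' Each sample is predicted by a model refit on the remaining n - 1;
#' \eqn{Q^2 = 1 - PRESS / \sum(y - \bar{y})^2} and
#' \eqn{RMSE_{LOO} = \sqrt{PRESS / n}}.
#'
#' @param fit_procedure function(X, y) returning an object with a
#'   `predict(object, newdata)` method.
#' @param X numeric matrix (n x p).
#' @param y numeric response.
#' @return Named vector `c(Q2_LOO, RMSE_LOO)`.
#' @export
q2_loo <- function(fit_procedure, X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 samples")
  preds <- vapply(seq_len(n), function(i) {
    fit <- tryCatch(fit_procedure(X[-i, , drop = FALSE], y[-i]),
                    error = function(e) {
                      stop(sprintf("leave-one-out fit failed on fold %d: %s",
                                   i, conditionMessage(e)), call. = FALSE)
                    })
    as.numeric(predict(fit, X[i, , drop = FALSE]))
  }, 0)
  press <- sum((y - preds)^2)
  c(Q2_LOO = 1 - press / sum((y - mean(y))^2),
    RMSE_LOO = sqrt(press / n))
}

#' External predictivity R2
#'
#' \eqn{1 - \sum(y - \hat{y})^2 / \sum(y - \bar{y}_{train})^2}: residuals of
#' the test set against the training-set mean as the null model.
#'
#' @param y_test,yhat_test test observations and predictions.
#' @param ybar_train training-set mean of the response.
#' @return R2_PRED (unitless).
#' @export
r2_pred <- function(y_test, yhat_test, ybar_train) {
  check_lengths(y_test, yhat_test)
  if (!length(y_test)) stop("need at least one test sample")
  denom <- sum((y_test - ybar_train)^2)
  if (denom == 0) stop("zero denominator: test set equals the training mean")
  1 - sum((y_test - yhat_test)^2) / denom
}

#' Roy rm2 validation metrics
#'
#' With \eqn{r^2} the squared Pearson correlation and \eqn{r_0^2} the
#' through-origin determination
#' \eqn{1 - \sum(obs - k\,pred)^2/\sum(obs - \bar{obs})^2},
#' \eqn{k = \sum obs\cdot pred / \sum pred^2}:
#' \eqn{rm^2 = r^2 (1 - \sqrt{|r^2 - r_0^2|})}; the primed variant swaps
#' the roles of the two vectors; the mean and absolute difference complete
#' the family.
#'
#' @param obs,pred numeric vectors (n >= 3, non-constant).
#' @return Named vector `c(rm2, rm2_prime, rm2_mean, delta_rm2)`.
#' @export
rm2_metrics <- function(obs, pred) {
  one_direction <- function(a, b) {
    r2 <- pearson_r2(a, b)
    k <- sum(a * b) / sum(b^2)
    r02 <- 1 - sum((a - k * b)^2) / sum((a - mean(a))^2)
    r2 * (1 - sqrt(abs(r2 - r02)))
  }
  rm2 <- one_direction(obs, pred)
  rm2p <- one_direction(pred, obs)
  c(rm2 = rm2, rm2_prime = rm2p, rm2_mean = (rm2 + rm2p) / 2,
    delta_rm2 = abs(rm2 - rm2p))
}

#' Lin's concordance correlation coefficient
#'
#' \eqn{2\sum(x-\bar x)(y-\bar y) / [\sum(x-\bar x)^2 + \sum(y-\bar y)^2 +
#' n(\bar x - \bar y)^2]}. Penalizes location and scale shifts, so
#' \eqn{|CCC| \le |r|}.
#'
#' @param x,y numeric vectors (n >= 2).
#' @return CCC in \[-1, 1\].
#' @export
ccc <- function(x, y) {
  check_lengths(x, y)
  if (length(x) < 2L) stop("need at least 2 pairs")
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  denom <- sum((x - mean(x))^2) + sum((y - mean(y))^2) +
    length(x) * (mean(x) - mean(y))^2
  if (denom == 0) stop("CCC undefined: both inputs constant and equal")
  2 * sxy / denom
}

#' Relative importance of linear-model terms
#'
#' Ranks each descriptor by |coefficient| x sd(column) over a descriptor
#' matrix -- the contribution spread of each term on the modelled panel.
#' Ties break alphabetically by name.
#'
#' @param model a `linear_descriptor_model`.
#' @param X data.frame or matrix with one column per model term.
#' @return data.frame with `name` and `importance`, descending.
#' @export
relative_importance <- function(model, X) {
  X <- as.data.frame(X)
  miss <- setdiff(names(model$terms), colnames(X))
  if (length(miss)) {
    stop("missing descriptor column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(X) < 2L) stop("need at least 2 rows")
  imp <- vapply(names(model$terms), function(nm)
    abs(model$terms[[nm]]) * stats::sd(X[[nm]]), 0)
  ord <- order(-imp, names(imp))
  data.frame(name = names(imp)[ord], importance = unname(imp[ord]),
             row.names = NULL)
}

#' Full validation report for a fitting procedure
#'
#' Fits on the training partition and assembles the complete printed
#' metric row: internal n, RMSE, R2 (residual form), RMSE_LOO, Q2_LOO;
#' external n, RMSE, R2 (trendline), R2_PRED, rm2 family and CCC.
#'
#' @param fit_procedure function(X, y) with a `predict` method.
#' @param train,test lists with elements `X` (matrix) and `y` (numeric);
#'   the partitions must be disjoint (checked via row names when present).
#' @return A list of class `validation_report`.
#' @export
validation_report <- function(fit_procedure, train, test) {
  trn <- rownames(as.matrix(train$X)); tst <- rownames(as.matrix(test$X))
  if (!is.null(trn) && !is.null(tst) && length(intersect(trn, tst))) {
    stop("training and test partitions must be disjoint")
  }
  if (identical(dim(as.matrix(train$X)), dim(as.matrix(test$X))) &&
      isTRUE(all.equal(as.matrix(train$X), as.matrix(test$X)))) {
    stop("training and test partitions must be disjoint")
  }
  fit <- fit_procedure(as.matrix(train$X), train$y)
  yhat_tr <- as.numeric(predict(fit, as.matrix(train$X)))
  yhat_te <- as.numeric(predict(fit, as.matrix(test$X)))
  loo <- q2_loo(fit_procedure, train$X, train$y)
  rm2 <- rm2_metrics(test$y, yhat_te)
  rep <- list(
    n_train = length(train$y),
    RMSE = rmse(train$y, yhat_tr),
    R2 = r2_fit(train$y, yhat_tr),
    RMSE_LOO = unname(loo["RMSE_LOO"]),
    Q2_LOO = unname(loo["Q2_LOO"]),
    n_test = length(test$y),
    RMSE_test = rmse(test$y, yhat_te),
    R2_test = pearson_r2(test$y, yhat_te),
    R2_PRED = r2_pred(test$y, yhat_te, mean(train$y)),
    rm2 = unname(rm2["rm2"]),
    rm2_prime = unname(rm2["rm2_prime"]),
    rm2_mean = unname(rm2["rm2_mean"]),
    delta_rm2 = unname(rm2["delta_rm2"]),
    CCC = ccc(test$y, yhat_te))
  class(rep) <- "validation_report"
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report> internal n=%d RMSE=%.2f R2=%.2f RMSE_LOO=%.2f Q2_LOO=%.2f\n",
    x$n_train, x$RMSE, x$R2, x$RMSE_LOO, x$Q2_LOO))
  cat(sprintf(
    "  external n=%d RMSE=%.2f R2=%.2f R2_PRED=%.2f rm2=%.2f rm2_mean=%.2f d_rm2=%.2f CCC=%.2f\n",
    x$n_test, x$RMSE_test, x$R2_test, x$R2_PRED, x$rm2, x$rm2_mean,
    x$delta_rm2, x$CCC))
  invisible(x)
}

#' Acceptability predicate for a validation report
#'
#' The printed acceptance thresholds as a checkable predicate:
#' R2 > 0.50, Q2_LOO > 0.50, RMSE < 0.50, R2_PRED > 0.50, rm2 >= 0.65,
#' CCC >= 0.85 and delta_rm2 <= 0.2.
#'
#' @param report a [validation_report()].
#' @return TRUE/FALSE, with a `checks` attribute naming each comparison.
#' @export
meets_acceptance_thresholds <- function(report) {
  checks <- c(
    R2 = report$R2 > 0.50,
    Q2_LOO = report$Q2_LOO > 0.50,
    RMSE = report$RMSE < 0.50,
    R2_PRED = report$R2_PRED > 0.50,
    rm2 = report$rm2 >= 0.65,
    CCC = report$CCC >= 0.85,
    delta_rm2 = report$delta_rm2 <= 0.2)
  structure(all(checks), checks = checks)
}
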