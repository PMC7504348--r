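# Validation-metric suite: hand-computed cases, dual-route oracles and
# the printed threshold predicate.

test_that("rmse matches hand arithmetic and scales correctly", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(1, -1)), 1)
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(rmse(3 * a, 3 * b), 3 * rmse(a, b), tolerance = 1e-12)
  expect_error(rmse(1:3, 1:2), "equal length")
})

test_that("the two R-squared forms are distinct and correct", {
  # trendline form: perfect linearity gives 1 regardless of offset
  x <- c(1, 2, 3, 4); y <- 2 * x + 5
  expect_equal(pearson_r2(x, y), 1)
  # residual form on the same data is poor (offset predictions)
  expect_lt(r2_fit(x, y), 0)
  expect_equal(r2_fit(x, x), 1)
  expect_equal(r2_fit(c(1, 2, 3), c(2, 2, 2)), 0)
  expect_equal(r2_fit(c(1, 2, 3), c(3, 2, 1)), -3)
  expect_error(pearson_r2(c(1, 1, 1), 1:3), "constant")
  expect_error(pearson_r2(1:2, 2:3), "at least 3")
})

test_that("pearson_r2 is affine-invariant; CCC is not", {
  withr::with_seed(8, { x <- rnorm(20); y <- x + rnorm(20, sd = 0.3) })
  expect_equal(pearson_r2(2 * x + 1, y), pearson_r2(x, y), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(ccc(2 * x + 1, y), ccc(x, y))))
  expect_lte(abs(ccc(x, y)), abs(cor(x, y)) + 1e-12)
})

test_that("CCC matches its defining formula", {
  expect_equal(ccc(1:5, 1:5), 1)
  expect_equal(ccc(c(1, 2, 3), c(2, 3, 4)), 4 / 7, tolerance = 1e-12)
  expect_error(ccc(c(1, 1), c(1, 1)), "undefined")
})

test_that("r2_pred uses the training mean as null model", {
  expect_equal(r2_pred(c(1, 2), c(1, 2), 5), 1)
  expect_equal(r2_pred(c(1, 3), c(2, 2), 2), 0)
  y <- c(4, 5, 6)
  expect_equal(r2_pred(y, rep(5, 3), 5), 0)
  expect_error(r2_pred(c(2, 2), c(1, 1), 2), "denominator")
})

test_that("rm2 family matches an independently coded oracle", {
  # second route: literal transcription of the defining formulas
  oracle_rm2 <- function(obs, pred) {
    dir <- function(a, b) {
      r2 <- cor(a, b)^2
      k <- sum(a * b) / sum(b * b)
      r02 <- 1 - sum((a - k * b)^2) / sum((a - mean(a))^2)
      r2 * (1 - sqrt(abs(r2 - r02)))
    }
    c(dir(obs, pred), dir(pred, obs))
  }
  obs <- c(1, 2, 3, 4); pred <- c(1.1, 1.9, 3.2, 3.8)
  got <- rm2_metrics(obs, pred)
  want <- oracle_rm2(obs, pred)
  expect_equal(unname(got["rm2"]), want[1], tolerance = 1e-12)
  expect_equal(unname(got["rm2_prime"]), want[2], tolerance = 1e-12)
  expect_equal(unname(got["rm2_mean"]), mean(want), tolerance = 1e-12)
  expect_equal(unname(got["delta_rm2"]), abs(diff(want)), tolerance = 1e-12)
  # identical vectors give (1, 1, 1, 0)
  expect_equal(unname(rm2_metrics(obs, obs)), c(1, 1, 1, 0))
  # delta is symmetric under swapping roles
  expect_equal(unname(rm2_metrics(obs, pred)["delta_rm2"]),
               unname(rm2_metrics(pred, obs)["delta_rm2"]))
})

test_that("q2_loo equals a brute-force refit-per-sample oracle", {
  sim <- simulate_qsar(n = 15, p = 3, beta = c(1, -1, 0.5), sigma = 0.2,
                       rho = 0.2, seed = 13)
  fitter <- function(X, y) pls_fit(X, y, 3)
  got <- q2_loo(fitter, sim$X, sim$y)
  # oracle: explicit per-fold lm refits (full-component PLS equals MLR)
  preds <- vapply(seq_len(15), function(i) {
    d <- data.frame(y = sim$y[-i], sim$X[-i, ])
    fit <- lm(y ~ ., data = d)
    predict(fit, data.frame(sim$X)[i, ])
  }, 0)
  press <- sum((sim$y - preds)^2)
  expect_equal(unname(got["Q2_LOO"]),
               1 - press / sum((sim$y - mean(sim$y))^2), tolerance = 1e-8)
  expect_equal(unname(got["RMSE_LOO"]), sqrt(press / 15), tolerance = 1e-8)
})

test_that("q2_loo behaves at the signal extremes", {
  withr::with_seed(31, {
    X <- matrix(rnorm(40), ncol = 2)
    y <- 2 * X[, 1] - X[, 2]
  })
  fitter <- function(X, y) pls_fit(X, y, 2)
  expect_gte(unname(q2_loo(fitter, X, y)["Q2_LOO"]), 0.999)
  # pure noise gives non-positive Q2 in expectation
  q2s <- vapply(1:25, function(seed) {
    withr::with_seed(seed + 500, {
      Xn <- matrix(rnorm(36), ncol = 2)
      yn <- rnorm(18)
    })
    unname(q2_loo(fitter, Xn, yn)["Q2_LOO"])
  }, 0)
  expect_lt(mean(q2s), 0)
})

test_that("relative importance ranks |coef| x sd and breaks ties by name", {
  m <- published_model("AChE")
  withr::with_seed(2, {
    X <- as.data.frame(matrix(rnorm(60), 10, 6))
  })
  names(X) <- names(m$terms)
  imp <- relative_importance(m, X)
  expect_equal(nrow(imp), 6L)
  expect_true(all(diff(imp$importance) <= 1e-12))
  # zero-variance column scores zero; doubling spread doubles the score
  X2 <- X; X2$reactive <- 0
  imp2 <- relative_importance(m, X2)
  expect_equal(imp2$importance[imp2$name == "reactive"], 0)
  X3 <- X; X3$SMR_VSA2 <- 2 * X3$SMR_VSA2
  imp3 <- relative_importance(m, X3)
  expect_equal(imp3$importance[imp3$name == "SMR_VSA2"],
               2 * imp$importance[imp$name == "SMR_VSA2"], tolerance = 1e-12)
  expect_error(relative_importance(m, X[, -1]), "missing descriptor")
})

test_that("validation reports assemble all printed metrics coherently", {
  sim <- simulate_qsar(n = 80, p = 6, sigma = 0.05, rho = 0.3, seed = 17)
  split <- random_split(seq_len(80), seed = 17)
  fitter <- function(X, y) pls_fit(X, y, 4)
  rep <- validation_report(
    fitter,
    train = list(X = sim$X[split$train, ], y = sim$y[split$train]),
    test = list(X = sim$X[split$validation, ], y = sim$y[split$validation]))
  expect_equal(rep$n_train, 56L)
  expect_equal(rep$n_test, 24L)
  for (f in c("R2", "Q2_LOO", "R2_PRED")) expect_gt(rep[[f]], 0.9)
  expect_equal(rep$rm2_mean, (rep$rm2 + rep$rm2_prime) / 2, tolerance = 1e-12)
  expect_lte(rep$R2, 1)
  expect_true(abs(rep$CCC) <= 1)
  # train == test is rejected
  expect_error(validation_report(
    fitter, train = list(X = sim$X, y = sim$y),
    test = list(X = sim$X, y = sim$y)), "disjoint")
})

test_that("threshold predicate passes high signal and fails scrambled nulls", {
  sim <- simulate_qsar(n = 80, p = 6, sigma = 0.05, rho = 0.3, seed = 23)
  split <- random_split(seq_len(80), seed = 23)
  fitter <- function(X, y) pls_fit(X, y, 4)
  good <- validation_report(
    fitter,
    train = list(X = sim$X[split$train, ], y = sim$y[split$train]),
    test = list(X = sim$X[split$validation, ], y = sim$y[split$validation]))
  expect_true(meets_acceptance_thresholds(good))
  y_perm <- withr::with_seed(99, sample(sim$y))
  bad <- validation_report(
    fitter,
    train = list(X = sim$X[split$train, ], y = y_perm[split$train]),
    test = list(X = sim$X[split$validation, ], y = y_perm[split$validation]))
  expect_false(meets_acceptance_thresholds(bad))
})
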