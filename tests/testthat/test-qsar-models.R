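# Published linear models, PLS fitting, component selection and the
# random 70/30 split.

test_that("published models carry the printed coefficients", {
  ache <- published_model("AChE")
  expect_equal(ache$intercept, -0.928)
  expect_length(ache$terms, 6L)
  expect_equal(unname(ache$terms["BCUT_SLOGP_3"]), 2.348)
  expect_equal(unname(ache$terms["reactive"]), -0.150)

  bace <- published_model("BACE-1")
  expect_equal(bace$intercept, 1.268)
  expect_length(bace$terms, 11L)
  expect_equal(unname(bace$terms["petitjean"]), 0.870)
  expect_equal(unname(bace$terms["BCUT_PEOE_1"]), 6.370)
  expect_equal(unname(bace$terms["logS"]), -0.260)
  expect_error(published_model("MAO-B"), "unknown target")
})

test_that("model prediction is the stated affine form", {
  ache <- published_model("AChE")
  zero <- stats::setNames(rep(0, 6), names(ache$terms))
  expect_equal(predict(ache, zero), -0.928)
  one_term <- zero; one_term["BCUT_SLOGP_3"] <- 2.5
  expect_equal(predict(ache, one_term), -0.928 + 2.348 * 2.5)
  bace <- published_model("BACE-1")
  zero11 <- stats::setNames(rep(0, 11), names(bace$terms))
  expect_equal(predict(bace, zero11), 1.268)
  expect_error(predict(ache, zero[-1]), "missing descriptor")
})

test_that("prediction honours superposition over descriptor values", {
  ache <- published_model("AChE")
  x1 <- stats::setNames(runif(6), names(ache$terms))
  x2 <- stats::setNames(runif(6), names(ache$terms))
  a <- 0.3; b <- 1.2
  lhs <- predict(ache, a * x1 + b * x2)
  rhs <- a * predict(ache, x1) + b * predict(ache, x2) +
    (1 - a - b) * ache$intercept
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("PLS reduces to least squares in the identifiable cases", {
  withr::with_seed(3, {
    x <- matrix(rnorm(60), ncol = 1)
    y <- 1.5 * x[, 1] + rnorm(60, sd = 0.1)
  })
  f1 <- pls_fit(x, y, 1)
  expect_equal(unname(coef(f1)), unname(coef(lm(y ~ x))), tolerance = 1e-9)

  # noiseless response is reproduced exactly at full rank
  sim <- simulate_qsar(n = 50, p = 4, beta = c(1, -2, 0.5, 3), sigma = 0,
                       seed = 5)
  ffull <- pls_fit(sim$X, sim$y, 4)
  expect_lt(max(abs(predict(ffull, sim$X) - sim$y)), 1e-8)

  # full-component PLS equals multiple linear regression predictions
  sim2 <- simulate_qsar(n = 80, p = 5, sigma = 0.3, rho = 0.4, seed = 6)
  fpls <- pls_fit(sim2$X, sim2$y, 5)
  mlr <- lm(sim2$y ~ sim2$X)
  expect_lt(max(abs(predict(fpls, sim2$X) - fitted(mlr))), 1e-6)
})

test_that("PLS recovers known coefficients from collinear simulations", {
  rel_err <- vapply(1:20, function(seed) {
    sim <- simulate_qsar(n = 200, p = 6, sigma = 0.05, rho = 0.3,
                         seed = seed)
    beta_hat <- coef(pls_fit(sim$X, sim$y, 6))[-1]
    mean(abs(beta_hat - sim$beta) / abs(sim$beta))
  }, 0)
  expect_lt(mean(rel_err), 0.05)
})

test_that("PLS agrees with an independent implementation", {
  sim <- simulate_qsar(n = 60, p = 5, sigma = 0.2, rho = 0.5, seed = 9)
  mine <- pls_fit(sim$X, sim$y, 2)
  theirs <- mixOmics::pls(sim$X, sim$y, ncomp = 2, mode = "regression",
                          scale = TRUE)
  pred_theirs <- predict(theirs, sim$X)$predict[, 1, 2]
  expect_equal(unname(predict(mine, sim$X)), unname(pred_theirs),
               tolerance = 1e-6)
})

test_that("rank deficiency yields fewer components with a warning", {
  X <- cbind(1:20, (1:20) * 2)  # rank 1
  y <- 1:20 + rnorm(20, sd = 0.01)
  expect_warning(f <- pls_fit(X, y, 2), "rank deficiency")
  expect_equal(f$n_components, 1L)
})

test_that("component selection maximizes leave-one-out Q2", {
  withr::with_seed(21, {
    x <- matrix(rnorm(40), ncol = 1)
    y <- 3 * x[, 1] + rnorm(40, sd = 0.1)
  })
  expect_equal(select_components_loo(x, y, 5), 1L)
  sim <- simulate_qsar(n = 60, p = 5, sigma = 0.1, rho = 0.2, seed = 2)
  k <- select_components_loo(sim$X, sim$y, 4)
  expect_lte(k, 4L); expect_gte(k, 1L)
  # pure-noise response: no count attains Q2 > 0
  withr::with_seed(22, {
    Xn <- matrix(rnorm(100), 20, 5)
    yn <- rnorm(20)
  })
  expect_warning(kn <- select_components_loo(Xn, yn, 3), "Q2 > 0")
  expect_equal(kn, 1L)
})

test_that("random 70/30 split reproduces the printed partition sizes", {
  s72 <- random_split(seq_len(72), seed = 4)
  expect_length(s72$train, 50L)
  expect_length(s72$validation, 22L)
  s215 <- random_split(seq_len(215), seed = 4)
  expect_length(s215$train, 150L)
  expect_length(s215$validation, 65L)
  expect_length(intersect(s72$train, s72$validation), 0L)
  expect_setequal(c(s72$train, s72$validation), seq_len(72))
})

test_that("splits are seed-deterministic and seed-sensitive", {
  a <- random_split(letters, seed = 10)
  b <- random_split(letters, seed = 10)
  expect_identical(a$train, b$train)
  c_ <- random_split(letters, seed = 11)
  expect_false(identical(a$train, c_$train))
  expect_error(random_split(1:2), "at least 3")
})

test_that("linear models serialize to flat JSON and back", {
  path <- withr::local_tempfile(fileext = ".json")
  m <- published_model("BACE-1")
  write_model_json(m, path)
  m2 <- read_model_json(path)
  expect_equal(m2$intercept, m$intercept)
  expect_equal(m2$terms, m$terms)
  x <- stats::setNames(runif(11), names(m$terms))
  expect_equal(predict(m2, x), predict(m, x), tolerance = 1e-12)
})
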