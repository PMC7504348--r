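# The two published linear descriptor models and PLS model building.

#' Published linear pIC50 model
#'
#' The two printed 2D-QSAR equations. The AChE model has 6 terms and the
#' BACE-1 model 11; predictions are
#' \eqn{\mathrm{pIC50} = \beta_0 + \sum_k \beta_k x_k} on raw (unscaled)
#' descriptor values.
#'
#' @param target `"AChE"` or `"BACE-1"` (case-insensitive; `"ache"`,
#'   `"bace1"` accepted).
#' @return An object of class `linear_descriptor_model` with fields
#'   `target`, `intercept` and named `terms`.
#' @export
published_model <- function(target) {
  key <- tolower(gsub("[^a-z0-9]", "", tolower(target)))
  if (key == "ache") {
    terms <- c("BCUT_SLOGP_3" = 2.348, "reactive" = -0.150,
               "PEOE_VSA+1" = -0.004, "PEOE_VSA-3" = -0.005,
               "SlogP_VSA2" = -0.002, "SMR_VSA2" = -0.004)
    model <- list(target = "AChE", intercept = -0.928, terms = terms)
  } else if (key %in% c("bace1", "bace")) {
    terms <- c("petitjean" = 0.870, "BCUT_PEOE_1" = 6.370, "a_ICM" = 3.305,
               "chiral_u" = -0.478, "rings" = 0.085, "a_Nn" = 0.157,
               "PEOE_VSA-0" = 0.006, "PEOE_VSA-6" = 0.022, "logS" = -0.260,
               "SlogP_VSA3" = 0.009, "SlogP_VSA5" = 0.009)
    model <- list(target = "BACE-1", intercept = 1.268, terms = terms)
  } else {
    stop("unknown target '", target, "'; use \"AChE\" or \"BACE-1\"")
  }
  class(model) <- "linear_descriptor_model"
  model
}

#' @export
print.linear_descriptor_model <- function(x, ...) {
  cat(sprintf("<linear_descriptor_model> %s: intercept %.3f + %d terms\n",
              x$target, x$intercept, length(x$terms)))
  invisible(x)
}

#' Predict pIC50 from a linear descriptor model
#'
#' @param object a `linear_descriptor_model`.
#' @param x named descriptor vector, a named list, or a data.frame /
#'   matrix with one column per descriptor (rows are molecules).
#' @param ... unused.
#' @return Numeric pIC50 prediction(s), not clipped or rounded.
#' @export
predict.linear_descriptor_model <- function(object, x, ...) {
  nms <- names(object$terms)
  if (is.data.frame(x) || is.matrix(x)) {
    miss <- setdiff(nms, colnames(x))
    if (length(miss)) {
      stop("missing descriptor(s): ", paste(miss, collapse = ", "))
    }
    xm <- as.matrix(as.data.frame(x)[, nms, drop = FALSE])
    return(unname(object$intercept + drop(xm %*% object$terms)))
  }
  x <- unlist(x)
  miss <- setdiff(nms, names(x))
  if (length(miss)) {
    stop("missing descriptor(s): ", paste(miss, collapse = ", "))
  }
  unname(object$intercept + sum(object$terms * x[nms]))
}

#' Fit a PLS regression model (NIPALS)
#'
#' Iterative NIPALS extraction of latent components on column-centred and
#' (by default) unit-variance-scaled data. Deterministic for fixed input.
#' Constant columns are tolerated (their scale is set to 1); if the
#' residual X matrix degenerates before `n_components` components are
#' extracted, the model is returned with fewer components and a warning.
#'
#' @param X numeric matrix (n x p).
#' @param y numeric response length n.
#' @param n_components number of latent components.
#' @param scale logical; autoscale columns to unit variance (default TRUE).
#' @param tol convergence tolerance for the NIPALS inner loop.
#' @return An object of class `pls_model`.
#' @export
pls_fit <- function(X, y, n_components, scale = TRUE, tol = 1e-10) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 2L) stop("need at least two samples")
  if (length(y) != n) stop("y must have length nrow(X)")
  if (stats::sd(y) == 0) stop("y must not be constant")
  if (n_components > min(n - 1L, p)) {
    stop("n_components must be <= min(n - 1, n_features)")
  }
  x_center <- colMeans(X)
  x_scale <- if (scale) apply(X, 2, stats::sd) else rep(1, p)
  x_scale[x_scale == 0] <- 1
  y_center <- mean(y)
  Xc <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  yc <- y - y_center

  W <- matrix(0, p, n_components)   # X weights
  P <- matrix(0, p, n_components)   # X loadings
  Tm <- matrix(0, n, n_components)  # scores
  b <- numeric(n_components)        # inner regression coefficients
  A <- 0L
  Xr <- Xc; yr <- yc
  for (a in seq_len(n_components)) {
    w <- drop(crossprod(Xr, yr))
    wn <- sqrt(sum(w^2))
    if (wn < tol) break
    w <- w / wn
    t <- drop(Xr %*% w)
    tt <- sum(t^2)
    if (tt < tol) break
    pvec <- drop(crossprod(Xr, t)) / tt
    ba <- sum(t * yr) / tt
    W[, a] <- w; P[, a] <- pvec; Tm[, a] <- t; b[a] <- ba
    Xr <- Xr - tcrossprod(t, pvec)
    yr <- yr - ba * t
    A <- a
  }
  if (A < n_components) {
    warning(sprintf("rank deficiency: extracted %d of %d components", A,
                    n_components))
    W <- W[, seq_len(A), drop = FALSE]
    P <- P[, seq_len(A), drop = FALSE]
    Tm <- Tm[, seq_len(A), drop = FALSE]
    b <- b[seq_len(A)]
  }
  # regression coefficients on the centred/scaled space
  R <- W %*% solve(crossprod(P, W))
  beta_cs <- drop(R %*% b)
  model <- list(n_components = A, weights = W, loadings = P, scores = Tm,
                inner = b, coef = beta_cs, x_center = x_center,
                x_scale = x_scale, y_center = y_center,
                feature_names = colnames(X))
  class(model) <- "pls_model"
  model
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d component(s), %d feature(s)\n",
              x$n_components, length(x$coef)))
  invisible(x)
}

#' Coefficients of a PLS model on the original scale
#'
#' @param object a `pls_model`.
#' @param ... unused.
#' @return Named vector with an `(Intercept)` entry.
#' @export
coef.pls_model <- function(object, ...) {
  beta <- object$coef / object$x_scale
  intercept <- object$y_center - sum(object$x_center * beta)
  stats::setNames(c(intercept, beta),
                  c("(Intercept)", object$feature_names))
}

#' @export
predict.pls_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$feature_names) && !is.null(colnames(X))) {
    X <- X[, object$feature_names, drop = FALSE]
  }
  Xc <- sweep(sweep(X, 2, object$x_center), 2, object$x_scale, "/")
  drop(object$y_center + Xc %*% object$coef)
}

#' Choose the PLS component count by leave-one-out Q2
#'
#' Fits 1..`max_components` and returns the count maximizing leave-one-out
#' \eqn{Q^2}; ties break to the smallest count. If no count achieves
#' \eqn{Q^2 > 0} (pure-noise response), 1 is returned with a warning.
#'
#' @param X,y as in [pls_fit()].
#' @param max_components upper bound (clamped to `min(n - 2, p)`).
#' @param scale passed to [pls_fit()].
#' @return Integer component count.
#' @export
select_components_loo <- function(X, y, max_components = 10L, scale = TRUE) {
  X <- as.matrix(X)
  max_components <- min(max_components, nrow(X) - 2L, ncol(X))
  if (max_components < 1L) stop("max_components must be >= 1")
  q2 <- vapply(seq_len(max_components), function(a) {
    fit <- function(Xtr, ytr) pls_fit(Xtr, ytr, a, scale = scale)
    q2_loo(fit, X, y)[["Q2_LOO"]]
  }, 0)
  if (all(q2 <= 0)) {
    warning("no component count achieves Q2 > 0; returning 1")
    return(1L)
  }
  which.max(q2)
}

#' Random 70/30 training/validation split
#'
#' Each id draws a uniform deviate from the seeded generator; the ids with
#' the smallest `floor(fraction * N)` deviates form the training set
#' (ties, a measure-zero event, break by id order).
#'
#' @param ids vector of identifiers (N >= 3).
#' @param fraction training fraction (default 0.7).
#' @param seed integer seed.
#' @return List with `train`, `validation`, `seed` (class `data_split`).
#' @export
random_split <- function(ids, fraction = 0.7, seed = 1L) {
  if (length(ids) < 3L) stop("need at least 3 ids")
  if (anyDuplicated(ids)) stop("ids must be unique")
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  u <- stats::runif(length(ids))
  n_train <- floor(fraction * length(ids))
  ord <- order(u, seq_along(ids))
  train_idx <- sort(ord[seq_len(n_train)])
  out <- list(train = ids[train_idx], validation = ids[-train_idx],
              seed = seed)
  class(out) <- "data_split"
  out
}

#' @export
print.data_split <- function(x, ...) {
  cat(sprintf("<data_split> %d train / %d validation (seed %s)\n",
              length(x$train), length(x$validation), format(x$seed)))
  invisible(x)
}

# save/restore the global RNG state so seeded helpers do not perturb
# the caller's stream
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Serialize / deserialize a linear descriptor model as flat JSON
#'
#' @param model a `linear_descriptor_model`.
#' @param path output file.
#' @return `write_model_json` returns `path` invisibly; `read_model_json`
#'   returns the model.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(
    list(target = model$target, intercept = model$intercept,
         terms = as.list(model$terms)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- list(target = obj$target, intercept = obj$intercept,
                terms = unlist(obj$terms))
  class(model) <- "linear_descriptor_model"
  model
}
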