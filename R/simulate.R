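# Seeded synthetic-data generators: descriptor matrices with controlled
# collinearity plus a linear response (the structure the QSAR stage
# assumes), and Ellman-plate absorbance readings consistent with a
# log-linear inhibition curve. A single seeded pseudo-random source per
# call; the caller's RNG state is left untouched.

#' Simulate a QSAR descriptor matrix and response
#'
#' X columns are standard normal with pairwise (equicorrelated) correlation
#' `rho`; the response is `intercept + X beta + N(0, sigma^2)`. Column
#' names default to the AChE model terms when p = 6 so end-to-end demos
#' run against [published_model()] shapes.
#'
#' @param n samples (> p).
#' @param p features (>= 1).
#' @param beta true coefficient vector (recycled to length p).
#' @param intercept true intercept.
#' @param sigma Gaussian noise SD (>= 0).
#' @param rho pairwise column correlation in \[0, 1).
#' @param seed integer seed.
#' @return List of class `qsar_simulation`: `X`, `y`, `beta`, `intercept`,
#'   `sigma`, `rho`, `seed`.
#' @export
simulate_qsar <- function(n = 200L, p = 6L, beta = c(1, -0.8, 0.6, -0.4,
                                                     0.3, 0.2),
                          intercept = 1, sigma = 0.05, rho = 0.3,
                          seed = 1L) {
  if (p < 1L || n <= p) stop("need n > p >= 1")
  if (sigma < 0) stop("sigma must be >= 0")
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  beta <- rep_len(beta, p)
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  common <- stats::rnorm(n)
  Z <- matrix(stats::rnorm(n * p), n, p)
  X <- sqrt(rho) * common + sqrt(1 - rho) * Z
  colnames(X) <- if (p == length(.ache_descriptor_names)) {
    .ache_descriptor_names
  } else {
    paste0("x", seq_len(p))
  }
  y <- intercept + drop(X %*% beta) + stats::rnorm(n, sd = sigma)
  structure(list(X = X, y = y, beta = beta, intercept = intercept,
                 sigma = sigma, rho = rho, seed = seed),
            class = "qsar_simulation")
}

#' Simulate Ellman-plate absorbance readings
#'
#' Percent inhibition is generated from the log-linear model anchored at
#' (IC50, 50%) with the given slope per log10 unit, then converted back to
#' the four absorbances of the percent-inhibition equation (enzyme control
#' window `a0e - a0`, compound blank `a0c`) with Gaussian absorbance noise
#' on the tested-sample wells.
#'
#' @param ic50_um named vector of true IC50s (uM), one per compound.
#' @param conc_um concentration grid (uM); default half-log spacing
#'   0.1-100.
#' @param slope percent inhibition per log10 concentration unit.
#' @param sigma absorbance noise SD (AU) on the tested wells; 2% of the
#'   control window by default.
#' @param replicates replicate count (triplicate by default).
#' @param a0e,a0,a0c control absorbances (AU).
#' @param seed integer seed.
#' @return List of class `plate_simulation`: `plate` (data.frame in
#'   [read_plate_csv()] layout) plus the generating parameters.
#' @export
simulate_plate <- function(ic50_um, conc_um = 10^seq(-1, 2, by = 0.5),
                           slope = 30, sigma = 0.02 * (a0e - a0),
                           replicates = 3L, a0e = 1.0, a0 = 0.1,
                           a0c = 0.1, seed = 1L) {
  if (any(ic50_um <= 0)) stop("IC50s must be positive")
  if (a0e <= a0) stop("control window must be positive (a0e > a0)")
  ids <- names(ic50_um)
  if (is.null(ids)) ids <- paste0("cmpd", seq_along(ic50_um))
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  window <- a0e - a0
  rows <- list()
  for (i in seq_along(ic50_um)) {
    for (r in seq_len(replicates)) {
      pct <- 50 + slope * (log10(conc_um) - log10(ic50_um[i]))
      # invert %I = 100 * (window - (ac - a0c)) / window for ac
      ac <- a0c + window * (1 - pct / 100)
      ac <- ac + stats::rnorm(length(ac), sd = sigma)
      rows[[length(rows) + 1L]] <- data.frame(
        id = ids[i], replicate = r, conc_um = conc_um,
        a0e = a0e, a0 = a0, ac = ac, a0c = a0c)
    }
  }
  structure(list(plate = do.call(rbind, rows), ic50_um = ic50_um,
                 conc_um = conc_um, slope = slope, sigma = sigma,
                 replicates = replicates, a0e = a0e, a0 = a0, a0c = a0c,
                 seed = seed),
            class = "plate_simulation")
}
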