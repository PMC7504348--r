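# Enzyme-assay arithmetic: Ellman percent inhibition from plate
# absorbances, log-linear IC50 extrapolation, pIC50 conversion and
# replicate summaries.

#' Percent inhibition from Ellman plate absorbances
#'
#' \deqn{\%I = 100 \times \frac{(A_{0E} - A_0) - (A_c - A_{0C})}{A_{0E} - A_0}}
#' where \eqn{A_{0E}} is the enzyme control blank, \eqn{A_0} the blank,
#' \eqn{A_c} the tested sample and \eqn{A_{0C}} the compound blank.
#' The printed equation omits the factor of 100 while reporting
#' percentages; the implementation includes it.
#'
#' @param a0e,a0,ac,a0c absorbances (AU); vectorized.
#' @return Percent inhibition.
#' @export
percent_inhibition <- function(a0e, a0, ac, a0c) {
  window <- a0e - a0
  if (any(window == 0)) stop("zero control window: A0E must differ from A0")
  100 * (window - (ac - a0c)) / window
}

#' Extrapolate IC50 from a dose-response series
#'
#' Least-squares line \eqn{\%I = a + b \log_{10} C} through the
#' (concentration, percent-inhibition) points; the IC50 is the
#' concentration at 50% inhibition, \eqn{10^{(50 - a)/b}}. The result is
#' flagged `extrapolated` when it falls outside the tested range.
#'
#' @param conc concentrations (uM, > 0; at least 2 distinct values).
#' @param pct_inhibition matching percent-inhibition values.
#' @return IC50 in uM with attributes `slope`, `intercept`,
#'   `extrapolated`.
#' @export
ic50_from_series <- function(conc, pct_inhibition) {
  check_lengths(conc, pct_inhibition)
  if (any(conc <= 0)) stop("concentrations must be positive")
  if (length(unique(conc)) < 2L) {
    stop("need at least 2 distinct concentrations")
  }
  lx <- log10(conc)
  fit <- stats::lm(pct_inhibition ~ lx)
  a <- unname(stats::coef(fit)[1]); b <- unname(stats::coef(fit)[2])
  if (!is.finite(b) || abs(b) < 1e-12) {
    stop("zero slope: inhibition does not change with concentration")
  }
  ic50 <- 10^((50 - a) / b)
  structure(ic50, slope = b, intercept = a,
            extrapolated = ic50 < min(conc) || ic50 > max(conc))
}

#' Convert IC50 (uM) to pIC50
#'
#' \eqn{pIC50 = -\log_{10}(IC50\ \mathrm{in\ M}) = 6 - \log_{10}(IC50\ \mathrm{in\ \mu M})}.
#'
#' @param ic50_um IC50 in micromolar (> 0); vectorized.
#' @return pIC50.
#' @export
pic50 <- function(ic50_um) {
  if (any(!is.finite(ic50_um)) || any(ic50_um <= 0)) {
    stop("IC50 must be positive and finite")
  }
  6 - log10(ic50_um)
}

#' Replicate mean and standard deviation
#'
#' Arithmetic mean and sample SD (n - 1 denominator), as used for the
#' triplicate "value +/- SD" presentation.
#'
#' @param values numeric vector (n >= 2).
#' @return Named vector `c(mean, sd)`.
#' @export
replicate_summary <- function(values) {
  if (length(values) < 2L) stop("need at least 2 replicates")
  c(mean = mean(values), sd = stats::sd(values))
}

#' Read a plate CSV of absorbance readings
#'
#' Expected columns: `id`, `replicate`, `conc_um`, `a0e`, `a0`, `ac`,
#' `a0c` (one row per compound x replicate x concentration).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_plate_csv <- function(path) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "replicate", "conc_um", "a0e", "a0", "ac", "a0c")
  miss <- setdiff(need, names(p))
  if (length(miss)) {
    stop("plate CSV is missing column(s): ", paste(miss, collapse = ", "))
  }
  p
}

#' IC50/pIC50 table from plate readings
#'
#' Per compound, each replicate's dose-response series is converted to
#' percent inhibition and an IC50; replicate IC50s (and their pIC50s) are
#' then summarized as mean +/- SD, matching the "IC50 +/- SD" presentation
#' (the pIC50 SD comes from the replicate pIC50s, which is why
#' \eqn{-\log_{10}} of the mean IC50 can differ from the mean pIC50 by a
#' rounding-level amount).
#'
#' @param plate data.frame as from [read_plate_csv()].
#' @return data.frame with one row per compound: `ic50_um`, `ic50_sd`,
#'   `pic50`, `pic50_sd`, `n_replicates`.
#' @export
ic50_table <- function(plate) {
  out <- lapply(split(plate, plate$id), function(d) {
    reps <- split(d, d$replicate)
    ic50s <- vapply(reps, function(r) {
      pct <- percent_inhibition(r$a0e, r$a0, r$ac, r$a0c)
      as.numeric(ic50_from_series(r$conc_um, pct))
    }, 0)
    pic50s <- pic50(ic50s)
    ic <- replicate_summary(ic50s)
    pc <- replicate_summary(pic50s)
    data.frame(id = d$id[1], ic50_um = ic[["mean"]], ic50_sd = ic[["sd"]],
               pic50 = pc[["mean"]], pic50_sd = pc[["sd"]],
               n_replicates = length(ic50s))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
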