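# Approximate van der Waals surface areas and subdivided-surface-area
# (VSA-type) descriptors: each heavy atom's accessible sphere area is the
# full vdW sphere minus the spherical caps occluded by its bonded
# neighbours (including its implicit hydrogens), evaluated at idealized
# bond lengths clamped to the geometric bounds |Ri - Rj| <= d <= Ri + Rj.
# Property bins then partition the total area by an atomic property
# (PEOE charge, Crippen logP or MR contribution).

# Bondi van der Waals radii (Angstrom)
.vdw_radius <- c(H = 1.20, B = 1.92, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
                 Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85,
                 I = 1.98)
# single-bond covalent radii (Cordero et al. consensus values, Angstrom)
.cov_radius <- c(H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
                 Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20,
                 I = 1.39)
# bond-length contraction by bond class (Angstrom)
.bond_contraction <- c(single = 0, aromatic = 0.075, double = 0.14,
                       triple = 0.24)

#' Default VSA configuration
#'
#' Radii, bond-length contractions and the property-bin boundary tables
#' used by the VSA descriptor family. All entries can be overridden, since
#' descriptor programs differ in dialect.
#'
#' @return A named list: `vdw_radius`, `cov_radius`, `bond_contraction`,
#'   `peoe_bins`, `slogp_bins`, `smr_bins`.
#' @export
vsa_config <- function() {
  list(vdw_radius = .vdw_radius, cov_radius = .cov_radius,
       bond_contraction = .bond_contraction,
       # PEOE charge bins: width 0.05 e spanning [-0.30, +0.30],
       # open terminal bins
       peoe_bins = seq(-0.30, 0.30, by = 0.05),
       # Crippen logP contribution bins
       slogp_bins = c(-0.40, -0.20, 0, 0.10, 0.15, 0.20, 0.25, 0.30, 0.40),
       # Crippen MR contribution bins
       smr_bins = c(1.29, 1.82, 2.24, 2.45, 2.75, 3.05, 3.63, 3.80))
}

#' Per-atom approximate van der Waals surface area
#'
#' Connection-table approximation: the exposed area of atom i is
#' \eqn{4\pi R_i^2} minus one spherical cap per bonded neighbour (implicit
#' hydrogens included as occluders), with cap height taken at the idealized
#' bond length \eqn{d_{ij} = r_i + r_j - c(\mathrm{order})} (covalent radii,
#' order-dependent contraction) clamped to
#' \eqn{|R_i - R_j| \le d_{ij} \le R_i + R_j}. Areas are floored at zero.
#'
#' @param m a [mol_graph()].
#' @param config see [vsa_config()].
#' @return Numeric vector of areas (Angstrom^2), one per heavy atom.
#' @export
approximate_vsa <- function(m, config = vsa_config()) {
  rv <- config$vdw_radius
  rc <- config$cov_radius
  contr <- config$bond_contraction
  el <- m$atoms$element
  unknown <- setdiff(unique(el), names(rv))
  if (length(unknown)) {
    stop("no van der Waals radius for element(s): ",
         paste(unknown, collapse = ", "))
  }
  R <- rv[el]
  area <- 4 * pi * R^2
  cap <- function(Ri, Rj, d) {
    d <- pmin(pmax(d, abs(Ri - Rj)), Ri + Rj)
    h <- Ri - (d^2 + Ri^2 - Rj^2) / (2 * d)
    2 * pi * Ri * pmax(h, 0)
  }
  b <- m$bonds
  if (nrow(b)) {
    cls <- ifelse(b$aromatic, "aromatic",
                  c("single", "double", "triple")[b$order])
    d <- rc[el[b$a1]] + rc[el[b$a2]] - contr[cls]
    for (k in seq_len(nrow(b))) {
      i <- b$a1[k]; j <- b$a2[k]
      area[i] <- area[i] - cap(R[i], R[j], d[k])
      area[j] <- area[j] - cap(R[j], R[i], d[k])
    }
  }
  # implicit hydrogens occlude their parent
  nh <- m$atoms$n_h
  if (any(nh > 0)) {
    dh <- rc[el] + rc["H"]
    area <- area - nh * cap(R, rv[["H"]], dh)
  }
  unname(pmax(area, 0))
}

#' Sum per-atom surface areas within property bins
#'
#' Generic engine behind the PEOE_VSA / SlogP_VSA / SMR_VSA families: each
#' atom's surface area is added to the half-open bin \eqn{(b_k, b_{k+1}]}
#' containing its property value; the first bin is \eqn{(-\infty, b_1]} and
#' the last \eqn{(b_K, \infty)}, giving `length(boundaries) + 1` sums.
#'
#' @param m a [mol_graph()].
#' @param property numeric per-atom property vector.
#' @param boundaries strictly ascending numeric boundaries.
#' @param vsa optional precomputed [approximate_vsa()] vector.
#' @param config see [vsa_config()].
#' @return Numeric vector of bin sums (Angstrom^2).
#' @export
binned_vsa <- function(m, property, boundaries, vsa = NULL,
                       config = vsa_config()) {
  if (length(property) != n_atoms(m)) {
    stop("property must have one value per heavy atom")
  }
  if (is.unsorted(boundaries, strictly = TRUE)) {
    stop("boundaries must be strictly ascending")
  }
  if (is.null(vsa)) vsa <- approximate_vsa(m, config)
  idx <- findInterval(property, boundaries, left.open = TRUE) + 1L
  out <- numeric(length(boundaries) + 1L)
  for (a in seq_along(idx)) out[idx[a]] <- out[idx[a]] + vsa[a]
  out
}

# named family helpers; names follow the common descriptor-program scheme
peoe_vsa_profile <- function(m, charges = NULL, config = vsa_config()) {
  if (is.null(charges)) charges <- peoe_charges(m)
  v <- binned_vsa(m, as.numeric(charges), config$peoe_bins, config = config)
  # bins: <=-0.30, (-0.30,-0.25], ..., (0.25,0.30], >0.30
  stats::setNames(v, c("PEOE_VSA-6", "PEOE_VSA-5", "PEOE_VSA-4", "PEOE_VSA-3",
                       "PEOE_VSA-2", "PEOE_VSA-1", "PEOE_VSA-0", "PEOE_VSA+0",
                       "PEOE_VSA+1", "PEOE_VSA+2", "PEOE_VSA+3", "PEOE_VSA+4",
                       "PEOE_VSA+5", "PEOE_VSA+6"))
}

slogp_vsa_profile <- function(m, contribs = NULL, config = vsa_config()) {
  if (is.null(contribs)) contribs <- crippen_contributions(m)
  v <- binned_vsa(m, contribs$slogp, config$slogp_bins, config = config)
  stats::setNames(v, paste0("SlogP_VSA", seq_along(v) - 1L))
}

smr_vsa_profile <- function(m, contribs = NULL, config = vsa_config()) {
  if (is.null(contribs)) contribs <- crippen_contributions(m)
  v <- binned_vsa(m, contribs$smr, config$smr_bins, config = config)
  stats::setNames(v, paste0("SMR_VSA", seq_along(v) - 1L))
}
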