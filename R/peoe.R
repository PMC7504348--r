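# Partial equalization of orbital electronegativities (PEOE) charges.
# Classic iterative Gasteiger-Marsili scheme: electronegativity of an atom
# is a quadratic in its charge, chi(q) = a + b q + c q^2; at each sweep k,
# charge (1/2)^k * (chi_j - chi_i) / chi_plus(donor) moves across each bond
# towards the more electronegative end. Charges are seeded with formal
# charges, so the total charge is conserved exactly.

# (a, b, c) by element and hybridization; chi_plus = a + b + c except for
# hydrogen where the cation value 20.02 is used (original parameterization).
.peoe_params <- list(
  "H"    = c(7.17, 6.24, -0.56),
  "C.3"  = c(7.98, 9.18, 1.88),
  "C.2"  = c(8.79, 9.32, 1.51),
  "C.1"  = c(10.39, 9.45, 0.73),
  "N.3"  = c(11.54, 10.82, 1.36),
  "N.2"  = c(12.87, 11.15, 0.85),
  "N.1"  = c(15.68, 11.70, -0.27),
  "O.3"  = c(14.18, 12.92, 1.39),
  "O.2"  = c(17.07, 13.79, 0.47),
  "F"    = c(14.66, 13.85, 2.31),
  "Cl"   = c(11.00, 9.69, 1.35),
  "Br"   = c(10.08, 8.47, 1.16),
  "I"    = c(9.90, 7.96, 0.96),
  "S.3"  = c(10.14, 9.13, 1.38),
  "P.3"  = c(8.90, 8.24, 0.96))

peoe_type <- function(element, hyb) {
  key <- switch(element,
    H = "H", F = "F", Cl = "Cl", Br = "Br", I = "I",
    C = paste0("C.", hyb),
    N = paste0("N.", min(hyb, 3L)),
    O = paste0("O.", if (hyb <= 2L) 2L else 3L),
    S = "S.3", P = "P.3",
    NULL)
  if (is.null(key) || is.null(.peoe_params[[key]])) {
    stop(sprintf("PEOE parameters are not available for element '%s'", element))
  }
  key
}

# 1 = sp, 2 = sp2, 3 = sp3 (by bond pattern; aromatic atoms are sp2)
atom_hybridization <- function(m) {
  n <- n_atoms(m)
  n_dbl <- integer(n); n_trp <- integer(n)
  b <- m$bonds
  for (k in seq_len(nrow(b))) {
    if (b$aromatic[k]) next
    if (b$order[k] == 2L) {
      n_dbl[b$a1[k]] <- n_dbl[b$a1[k]] + 1L
      n_dbl[b$a2[k]] <- n_dbl[b$a2[k]] + 1L
    } else if (b$order[k] == 3L) {
      n_trp[b$a1[k]] <- n_trp[b$a1[k]] + 1L
      n_trp[b$a2[k]] <- n_trp[b$a2[k]] + 1L
    }
  }
  hyb <- rep(3L, n)
  hyb[m$atoms$aromatic | n_dbl == 1L] <- 2L
  hyb[n_trp >= 1L | n_dbl >= 2L] <- 1L
  # lone-pair conjugation: saturated N/O adjacent to an aromatic ring or a
  # multiple bond is planar (sp2), as in aniline, amide and aryl-ether
  adj <- adjacency_list(m)
  for (i in which(hyb == 3L & m$atoms$element %in% c("N", "O"))) {
    nb <- adj[[i]]
    if (is.null(nb)) next
    js <- nb[, 1]
    if (any(m$atoms$aromatic[js] | n_dbl[js] > 0L | n_trp[js] > 0L)) {
      hyb[i] <- 2L
    }
  }
  hyb
}

#' PEOE (Gasteiger) partial charges
#'
#' Iterative partial equalization of orbital electronegativities with
#' damping factor \eqn{(1/2)^k} at sweep \eqn{k}. Hydrogens participate
#' explicitly in the iteration (each implicit hydrogen is expanded to its
#' own node); the returned vector holds the heavy-atom charges, with the
#' per-atom hydrogen-charge sums available as attribute `h_charge`.
#'
#' @param m a [mol_graph()].
#' @param n_iter number of damped sweeps (default 8; changes beyond that
#'   are below 1e-4 e).
#' @return Numeric vector of heavy-atom charges (e), attribute `h_charge`.
#' @export
peoe_charges <- function(m, n_iter = 8L) {
  n <- n_atoms(m)
  hyb <- atom_hybridization(m)
  types <- vapply(seq_len(n), function(i)
    peoe_type(m$atoms$element[i], hyb[i]), "")
  # expand implicit hydrogens into explicit nodes
  h_parent <- integer(0)
  for (i in seq_len(n)) {
    h_parent <- c(h_parent, rep(i, m$atoms$n_h[i]))
  }
  ntot <- n + length(h_parent)
  types <- c(types, rep("H", length(h_parent)))
  q <- c(as.numeric(m$atoms$charge), rep(0, length(h_parent)))
  edges <- rbind(
    as.matrix(m$bonds[, c("a1", "a2")]),
    cbind(n + seq_along(h_parent), h_parent))
  abc <- do.call(rbind, .peoe_params[types])
  chi_plus <- abc[, 1] + abc[, 2] + abc[, 3]
  chi_plus[types == "H"] <- 20.02
  damp <- 1
  for (k in seq_len(n_iter)) {
    damp <- damp / 2
    chi <- abc[, 1] + abc[, 2] * q + abc[, 3] * q * q
    if (nrow(edges)) {
      i <- edges[, 1]; j <- edges[, 2]
      lo <- ifelse(chi[i] <= chi[j], i, j)
      hi <- ifelse(chi[i] <= chi[j], j, i)
      dq <- (chi[hi] - chi[lo]) / chi_plus[lo] * damp
      for (e in seq_along(dq)) {
        q[lo[e]] <- q[lo[e]] + dq[e]
        q[hi[e]] <- q[hi[e]] - dq[e]
      }
    }
  }
  heavy <- q[seq_len(n)]
  hq <- numeric(n)
  if (length(h_parent)) {
    hsum <- tapply(q[n + seq_along(h_parent)], h_parent, sum)
    hq[as.integer(names(hsum))] <- hsum
  }
  attr(heavy, "h_charge") <- hq
  heavy
}
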