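# Burden-matrix eigenvalue (BCUT) descriptors. The Burden matrix is a
# symmetric heavy-atom matrix with an atomic property on the diagonal,
# 0.1 x bond order (0.15 for aromatic bonds) for bonded pairs, and 0.001
# for non-bonded pairs; BCUT_k descriptors are order statistics of its
# eigenvalue spectrum.

#' Burden-matrix eigenvalues
#'
#' @param m a [mol_graph()].
#' @param diag numeric per-heavy-atom diagonal property.
#' @return Eigenvalues sorted ascending.
#' @export
burden_eigenvalues <- function(m, diag) {
  n <- n_atoms(m)
  if (n < 1L) stop("molecule must have at least one atom")
  if (length(diag) != n) stop("diag must have one value per heavy atom")
  B <- matrix(0.001, n, n)
  b <- m$bonds
  if (nrow(b)) {
    off <- ifelse(b$aromatic, 0.15, 0.1 * b$order)
    for (k in seq_len(nrow(b))) {
      B[b$a1[k], b$a2[k]] <- off[k]
      B[b$a2[k], b$a1[k]] <- off[k]
    }
  }
  diag(B) <- diag
  sort(eigen(B, symmetric = TRUE, only.values = TRUE)$values)
}

#' BCUT descriptor
#'
#' Order statistics of the Burden eigenvalue spectrum with a Crippen-logP
#' (`"SLOGP"`) or PEOE-charge (`"PEOE"`) diagonal. Index 0 is the smallest
#' eigenvalue and 3 the largest; indices 1 and 2 are the eigenvalues at
#' positions `round((n-1)/3)` and `round(2*(n-1)/3)` of the ascending
#' spectrum (0-based).
#'
#' @param m a [mol_graph()].
#' @param property `"SLOGP"` or `"PEOE"`.
#' @param index 0, 1, 2 or 3.
#' @param diag optional precomputed diagonal (overrides `property`).
#' @return A single numeric value.
#' @export
bcut <- function(m, property = c("SLOGP", "PEOE"), index = 3L, diag = NULL) {
  property <- match.arg(property)
  if (!index %in% 0:3) stop("index must be 0, 1, 2 or 3")
  if (is.null(diag)) {
    diag <- switch(property,
      SLOGP = crippen_contributions(m)$slogp,
      PEOE = as.numeric(peoe_charges(m)))
  }
  ev <- burden_eigenvalues(m, diag)
  n <- length(ev)
  pos <- switch(as.character(index),
    "0" = 1L,
    "1" = round((n - 1) / 3) + 1L,
    "2" = round(2 * (n - 1) / 3) + 1L,
    "3" = n)
  ev[pos]
}
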