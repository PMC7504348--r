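# Molecular graph container: the substrate every 2D descriptor is computed on.
# Hydrogens are implicit (a per-atom count); all other atoms are explicit.

#' Construct a molecular graph
#'
#' A `mol_graph` is the hydrogen-suppressed molecular graph used throughout
#' the package: a table of heavy atoms (element, formal charge, implicit-H
#' count, aromatic flag, tetrahedral stereo tag) and a table of bonds
#' (endpoint indices, integer order, aromatic flag). It is normally produced
#' by [parse_structure()] rather than called directly.
#'
#' @param atoms data.frame with columns `element` (character symbol),
#'   `charge` (integer formal charge, e), `n_h` (non-negative integer
#'   implicit-hydrogen count), `aromatic` (logical), `stereo` (one of
#'   `"unspecified"`, `"R"`, `"S"`).
#' @param bonds data.frame with columns `a1`, `a2` (1-based atom indices),
#'   `order` (1, 2 or 3; aromatic bonds carry order 1 plus `aromatic = TRUE`),
#'   `aromatic` (logical).
#' @param name optional molecule name.
#' @return An object of class `mol_graph`.
#' @export
mol_graph <- function(atoms, bonds = NULL, name = "") {
  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0L) {
    bonds <- data.frame(a1 = integer(), a2 = integer(),
                        order = integer(), aromatic = logical())
  }
  atoms <- as.data.frame(atoms)
  bonds <- as.data.frame(bonds)
  need_a <- c("element", "charge", "n_h", "aromatic", "stereo")
  if (!all(need_a %in% names(atoms))) {
    stop("atoms must have columns: ", paste(need_a, collapse = ", "))
  }
  need_b <- c("a1", "a2", "order", "aromatic")
  if (!all(need_b %in% names(bonds))) {
    stop("bonds must have columns: ", paste(need_b, collapse = ", "))
  }
  m <- structure(list(atoms = atoms, bonds = bonds, name = name),
                 class = "mol_graph")
  validate_mol_graph(m)
  m
}

validate_mol_graph <- function(m) {
  a <- m$atoms; b <- m$bonds
  n <- nrow(a)
  if (nrow(b)) {
    if (any(b$a1 < 1 | b$a1 > n | b$a2 < 1 | b$a2 > n)) {
      stop("bond endpoints must index valid atoms")
    }
    if (any(b$a1 == b$a2)) stop("self-bonds are not allowed")
    key <- paste(pmin(b$a1, b$a2), pmax(b$a1, b$a2))
    if (anyDuplicated(key)) stop("duplicate bonds are not allowed")
    bad <- b$aromatic & !(a$aromatic[b$a1] & a$aromatic[b$a2])
    if (any(bad)) stop("aromatic bonds must join two aromatic atoms")
  }
  if (any(a$n_h < 0 | a$n_h != round(a$n_h))) {
    stop("implicit-H counts must be non-negative integers")
  }
  invisible(m)
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %s: %d heavy atoms, %d bonds, formula %s\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              nrow(x$atoms), nrow(x$bonds), molecular_formula(x)))
  invisible(x)
}

n_atoms <- function(m) nrow(m$atoms)

# neighbour list over heavy atoms; attr "order"/"aromatic" aligned per edge
adjacency_list <- function(m) {
  n <- n_atoms(m)
  adj <- vector("list", n)
  b <- m$bonds
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      i <- b$a1[k]; j <- b$a2[k]
      adj[[i]] <- rbind(adj[[i]], c(j, k))
      adj[[j]] <- rbind(adj[[j]], c(i, k))
    }
  }
  adj
}

mol_igraph <- function(m) {
  igraph::graph_from_data_frame(
    d = if (nrow(m$bonds)) m$bonds[, c("a1", "a2")] else
      data.frame(a1 = integer(), a2 = integer()),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n_atoms(m))))
}

# Monoisotopic masses of the most abundant isotope (CODATA/AME-derived,
# standard values) and average atomic weights.
.isotope_mass <- c(
  H = 1.0078250319, B = 11.0093054, C = 12.0, N = 14.0030740052,
  O = 15.9949146221, F = 18.9984031627, Si = 27.9769265, P = 30.97376151,
  S = 31.97207069, Cl = 34.96885268, Br = 78.9183376, I = 126.904473)
.average_mass <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904, I = 126.904)
.proton_mass <- 1.00727646

element_counts <- function(m) {
  els <- m$atoms$element
  cnt <- table(els)
  counts <- stats::setNames(as.integer(cnt), names(cnt))
  nh <- sum(m$atoms$n_h)
  if (nh > 0) counts["H"] <- (if ("H" %in% names(counts)) counts[["H"]] else 0L) + nh
  counts
}

#' Molecular formula in Hill order
#'
#' Element counts include implicit hydrogens. Hill order: carbon first,
#' hydrogen second, all other elements alphabetically (fully alphabetical
#' when no carbon is present).
#'
#' @param m a [mol_graph()].
#' @return A single string, e.g. `"C26H26N2OS"`.
#' @export
molecular_formula <- function(m) {
  counts <- element_counts(m)
  els <- names(counts)
  if ("C" %in% els) {
    rest <- sort(setdiff(els, c("C", "H")))
    ord <- c("C", if ("H" %in% els) "H", rest)
  } else {
    ord <- sort(els)
  }
  paste0(vapply(ord, function(e) {
    n <- counts[[e]]
    if (n == 1L) e else paste0(e, n)
  }, character(1)), collapse = "")
}

#' Monoisotopic protonated mass [M+H]+
#'
#' Monoisotopic mass of the neutral molecule plus one proton, using standard
#' isotope masses; used to check derived structures against printed HR-MS
#' m/z values.
#'
#' @param m a [mol_graph()].
#' @return Mass in Da.
#' @export
monoisotopic_mh <- function(m) {
  counts <- element_counts(m)
  unknown <- setdiff(names(counts), names(.isotope_mass))
  if (length(unknown)) {
    stop("no isotope mass for element(s): ", paste(unknown, collapse = ", "))
  }
  sum(.isotope_mass[names(counts)] * counts) + .proton_mass
}

#' Average molecular weight
#'
#' @param m a [mol_graph()].
#' @return Weight in g/mol (standard atomic weights, implicit H included).
#' @export
molecular_weight <- function(m) {
  counts <- element_counts(m)
  unknown <- setdiff(names(counts), names(.average_mass))
  if (length(unknown)) {
    stop("no atomic weight for element(s): ", paste(unknown, collapse = ", "))
  }
  sum(.average_mass[names(counts)] * counts)
}
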