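# Topological, count and physical-property descriptors.

#' Petitjean shape index
#'
#' \eqn{(D - R)/R} where D is the diameter and R the radius of the
#' heavy-atom graph under topological (bond-count) distances. Computed on
#' the largest connected component; a single atom gives 0 by convention.
#' Always in \[0, 1\] since \eqn{R \le D \le 2R}.
#'
#' @param m a [mol_graph()].
#' @return A value in \[0, 1\].
#' @export
petitjean_index <- function(m) {
  n <- n_atoms(m)
  if (n <= 1L) return(0)
  g <- mol_igraph(m)
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  if (length(keep) <= 1L) return(0)
  d <- igraph::distances(igraph::induced_subgraph(g, keep))
  ecc <- apply(d, 1, max)
  D <- max(ecc); R <- min(ecc)
  if (R == 0) return(0)
  (D - R) / R
}

#' Element-distribution entropy (a_ICM)
#'
#' Shannon entropy (base 2) of the element distribution over all atoms,
#' implicit hydrogens included. Single-element molecules give 0 bits.
#'
#' @param m a [mol_graph()].
#' @return Entropy in bits.
#' @export
a_icm <- function(m) {
  counts <- element_counts(m)
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

# candidate tetrahedral stereocentres: saturated carbon with four distinct
# substituent branches (implicit hydrogens count as one branch class);
# distinctness judged by canonical neighbour ranks
potential_stereocentres <- function(m) {
  rank <- canonical_ranks(m)
  adj <- adjacency_list(m)
  out <- integer()
  for (i in seq_len(n_atoms(m))) {
    if (m$atoms$element[i] != "C" || m$atoms$aromatic[i]) next
    nb <- adj[[i]]
    deg <- if (is.null(nb)) 0L else nrow(nb)
    if (deg + m$atoms$n_h[i] != 4L || m$atoms$n_h[i] > 1L) next
    if (!is.null(nb) && any(m$bonds$order[nb[, 2]] > 1L)) next
    codes <- rank[nb[, 1]]
    if (m$atoms$n_h[i] == 1L) codes <- c(codes, -1L)
    if (!anyDuplicated(codes)) out <- c(out, i)
  }
  out
}

#' Simple count descriptors
#'
#' * `rings`: smallest-set-of-smallest-rings size, computed as the
#'   cyclomatic number bonds - atoms + components of the heavy-atom graph;
#' * `a_Nn`: number of nitrogen atoms (the conventional descriptor name is
#'   `a_nN`; both spellings are accepted by [descriptor_vector()]);
#' * `chiral_u`: candidate tetrahedral stereocentres whose stereo tag is
#'   `"unspecified"`.
#'
#' @param m a [mol_graph()].
#' @return Named integer vector `c(rings, a_Nn, chiral_u)`.
#' @export
simple_counts <- function(m) {
  g <- mol_igraph(m)
  ncomp <- igraph::components(g)$no
  rings <- nrow(m$bonds) - n_atoms(m) + ncomp
  cand <- potential_stereocentres(m)
  chiral_u <- sum(m$atoms$stereo[cand] == "unspecified")
  c(rings = as.integer(rings),
    a_Nn = sum(m$atoms$element == "N"),
    chiral_u = as.integer(chiral_u))
}

#' Rotatable-bond count
#'
#' Non-ring single bonds between two heavy atoms that each carry at least
#' one further heavy neighbour (terminal bonds are rigid by definition).
#'
#' @param m a [mol_graph()].
#' @return Integer count.
#' @export
rotatable_bonds <- function(m) {
  b <- m$bonds
  if (!nrow(b)) return(0L)
  deg <- integer(n_atoms(m))
  for (k in seq_len(nrow(b))) {
    deg[b$a1[k]] <- deg[b$a1[k]] + 1L
    deg[b$a2[k]] <- deg[b$a2[k]] + 1L
  }
  inring <- bonds_in_ring(m$atoms, b)
  sum(b$order == 1L & !b$aromatic & !inring &
        deg[b$a1] >= 2L & deg[b$a2] >= 2L)
}

#' ESOL-style aqueous solubility surrogate (logS)
#'
#' Linear estimated-solubility model
#' \deqn{\log S = 0.16 - 0.63\,\mathrm{clogP} - 0.0062\,\mathrm{MW}
#'   + 0.066\,\mathrm{RB} - 0.74\,\mathrm{AP}}
#' with clogP the Crippen logP (hydrogens included), MW the average
#' molecular weight, RB the rotatable-bond count and AP the aromatic
#' proportion (aromatic heavy atoms / heavy atoms). This is a documented
#' linear surrogate for the solubility descriptor of descriptor programs
#' whose exact model is proprietary.
#'
#' @param m a [mol_graph()].
#' @return logS in log10 mol/L.
#' @export
log_solubility <- function(m) {
  clogp <- unname(crippen_logp(m)["logp"])
  mw <- molecular_weight(m)
  rb <- rotatable_bonds(m)
  ap <- mean(m$atoms$aromatic)
  0.16 - 0.63 * clogp - 0.0062 * mw + 0.066 * rb - 0.74 * ap
}

# --- reactive-group flag --------------------------------------------------

# built-in reactive-group graph predicates; each takes a mol_graph and
# returns TRUE on a match
.reactive_patterns <- list(
  acyl_halide = function(m) {
    ctxs <- crippen_context(m)
    any(vapply(ctxs, function(ctx) {
      ctx$el == "C" && !ctx$arom &&
        any(ctx$bond_order == 2L & !ctx$bond_arom & ctx$nbr_el == "O") &&
        any(ctx$bond_order == 1L & ctx$nbr_el %in% c("F", "Cl", "Br", "I"))
    }, TRUE))
  },
  alpha_halo_aldehyde = function(m) {
    ctxs <- crippen_context(m)
    adj <- adjacency_list(m)
    for (i in seq_len(n_atoms(m))) {
      ctx <- ctxs[[i]]
      if (ctx$el != "C" || ctx$arom || ctx$nh != 1L) next
      if (!any(ctx$bond_order == 2L & !ctx$bond_arom & ctx$nbr_el == "O")) next
      js <- adj[[i]][, 1]
      alpha <- js[m$atoms$element[js] == "C"]
      for (a in alpha) {
        if (any(ctxs[[a]]$nbr_el %in% c("F", "Cl", "Br", "I"))) return(TRUE)
      }
    }
    FALSE
  },
  anhydride = function(m) {
    ctxs <- crippen_context(m)
    adj <- adjacency_list(m)
    for (i in seq_len(n_atoms(m))) {
      ctx <- ctxs[[i]]
      if (ctx$el != "O" || ctx$arom || length(ctx$nbr_el) != 2L) next
      js <- adj[[i]][, 1]
      carbonyl <- vapply(js, function(j) {
        cj <- ctxs[[j]]
        cj$el == "C" &&
          any(cj$bond_order == 2L & !cj$bond_arom & cj$nbr_el == "O")
      }, TRUE)
      if (all(carbonyl)) return(TRUE)
    }
    FALSE
  },
  epoxide = function(m) {
    rings <- find_rings(m, max_size = 3L)
    for (r in rings) {
      els <- m$atoms$element[r]
      if (length(r) == 3L && sum(els == "O") == 1L && sum(els == "C") == 2L) {
        return(TRUE)
      }
    }
    FALSE
  },
  isocyanate = function(m) {
    ctxs <- crippen_context(m)
    any(vapply(ctxs, function(ctx) {
      ctx$el == "C" && !ctx$arom &&
        sum(ctx$bond_order == 2L & !ctx$bond_arom & ctx$nbr_el == "N") >= 1L &&
        sum(ctx$bond_order == 2L & !ctx$bond_arom & ctx$nbr_el == "O") >= 1L
    }, TRUE))
  },
  # Michael-acceptor enone C=C-C=O; OFF by default (every chalcone carries
  # one, see reactive_flag)
  enone = function(m) {
    ctxs <- crippen_context(m)
    adj <- adjacency_list(m)
    for (i in seq_len(n_atoms(m))) {
      ctx <- ctxs[[i]]
      if (ctx$el != "C" || ctx$arom) next
      if (!any(ctx$bond_order == 2L & !ctx$bond_arom & ctx$nbr_el == "O")) next
      js <- adj[[i]][, 1]
      vinyl <- js[m$atoms$element[js] == "C" & !m$atoms$aromatic[js]]
      for (v in vinyl) {
        cv <- ctxs[[v]]
        if (any(cv$bond_order == 2L & !cv$bond_arom & cv$nbr_el == "C" &
                  !cv$nbr_arom)) return(TRUE)
      }
    }
    FALSE
  })

#' Default reactive-group pattern list
#'
#' Named list of graph-predicate functions used by [reactive_flag()]:
#' acyl halide, alpha-halo aldehyde, anhydride, epoxide and isocyanate by
#' default; the Michael-acceptor `enone` pattern is available but excluded
#' from the default list (all 13 panel chalcones contain one, and enabling
#' it shifts every chalcone's AChE prediction by the constant
#' reactive-term coefficient).
#'
#' @param include_enone include the enone pattern.
#' @return Named list of functions.
#' @export
reactive_patterns <- function(include_enone = FALSE) {
  pats <- .reactive_patterns
  if (!include_enone) pats$enone <- NULL
  pats
}

#' Reactive-group indicator descriptor
#'
#' 1 if any pattern in the (configurable) reactive-group list matches,
#' else 0.
#'
#' @param m a [mol_graph()].
#' @param patterns named list of predicate functions; see
#'   [reactive_patterns()].
#' @return 0 or 1.
#' @export
reactive_flag <- function(m, patterns = reactive_patterns()) {
  if (!is.list(patterns) || (length(patterns) && is.null(names(patterns)))) {
    stop("patterns must be a named list of predicate functions")
  }
  for (nm in names(patterns)) {
    f <- patterns[[nm]]
    if (!is.function(f)) {
      stop(sprintf("reactive pattern '%s' is not a function", nm))
    }
    res <- f(m)
    if (!is.logical(res) || length(res) != 1L || is.na(res)) {
      stop(sprintf("reactive pattern '%s' must return TRUE or FALSE", nm))
    }
    if (res) return(1L)
  }
  0L
}
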