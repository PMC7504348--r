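# Helpers: random valid SMILES from safe fragments, and atom-order
# permutation of a mol_graph (for graph-invariance properties).

random_smiles <- function(n, seed = 1L) {
  frags <- c("C", "CC", "CO", "CN", "C(C)C", "C(=O)C", "C(=O)O", "CS",
             "c1ccccc1", "C1CCCCC1", "c1ccncc1", "CCl", "CBr", "C(F)(F)F",
             "COC", "CC#N", "c1ccco1", "C1CCNCC1")
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      k <- sample(1:4, 1)
      paste(sample(frags, k, replace = TRUE), collapse = "")
    }, "")
  })
}

permute_mol <- function(m, perm) {
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  atoms <- m$atoms[perm, , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- m$bonds
  bonds$a1 <- inv[bonds$a1]
  bonds$a2 <- inv[bonds$a2]
  mol_graph(atoms, bonds, name = m$name)
}

# build a simple random connected graph of carbons (tree plus extra edges)
random_carbon_graph <- function(n_atoms, extra_edges = 1L, seed = 1L) {
  withr::with_seed(seed, {
    atoms <- data.frame(element = rep("C", n_atoms), charge = 0L, n_h = 0L,
                        aromatic = FALSE, stereo = "unspecified")
    bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer(),
                        aromatic = logical())
    for (i in seq_len(n_atoms)[-1]) {
      bonds <- rbind(bonds, data.frame(a1 = sample(i - 1L, 1), a2 = i,
                                       order = 1L, aromatic = FALSE))
    }
    tries <- 0L
    while (extra_edges > 0L && tries < 50L && n_atoms >= 3L) {
      tries <- tries + 1L
      ij <- sort(sample(n_atoms, 2))
      if (!any(bonds$a1 == ij[1] & bonds$a2 == ij[2]) &&
          !any(bonds$a1 == ij[2] & bonds$a2 == ij[1])) {
        bonds <- rbind(bonds, data.frame(a1 = ij[1], a2 = ij[2],
                                         order = 1L, aromatic = FALSE))
        extra_edges <- extra_edges - 1L
      }
    }
    mol_graph(atoms, bonds)
  })
}
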