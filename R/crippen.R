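# Wildman-Crippen atomic logP / molar-refractivity contributions.
# The published atom-type table is encoded as ordered predicate rules over
# the molecular graph (first match wins, same precedence as the published
# SMARTS list); implicit hydrogens are typed from their heavy parent.

.crippen_values <- list(
  C1  = c(0.1441, 2.503),  C2  = c(0.0000, 2.433),  C3  = c(-0.2035, 2.753),
  C4  = c(-0.2051, 2.731), C5  = c(-0.2783, 5.007), C6  = c(0.1551, 3.513),
  C7  = c(0.0017, 3.888),  C8  = c(0.08452, 2.464), C9  = c(-0.1444, 2.412),
  C10 = c(-0.0516, 2.488), C11 = c(0.1193, 2.582),  C12 = c(-0.0967, 2.576),
  C13 = c(-0.5443, 4.041), C14 = c(0.0000, 3.257),  C15 = c(0.2450, 3.564),
  C16 = c(0.1980, 3.180),  C17 = c(0.0000, 3.104),  C18 = c(0.1581, 3.350),
  C19 = c(0.2955, 4.346),  C20 = c(0.2713, 3.904),  C21 = c(0.1360, 3.509),
  C22 = c(0.4619, 4.067),  C23 = c(0.5437, 3.853),  C24 = c(0.1893, 2.673),
  C25 = c(-0.8186, 3.135), C26 = c(0.2640, 4.305),  C27 = c(0.2148, 2.693),
  CS  = c(0.08129, 3.243),
  H1  = c(0.1230, 1.057),  H2  = c(-0.2677, 1.395), H3  = c(0.2142, 0.9627),
  H4  = c(0.2980, 1.805),  HS  = c(0.1125, 1.112),
  N1  = c(-1.0190, 2.262), N2  = c(-0.7096, 2.173), N3  = c(-1.0270, 2.827),
  N4  = c(-0.5188, 3.000), N5  = c(0.08387, 1.757), N6  = c(0.1836, 2.428),
  N7  = c(-0.3187, 1.839), N8  = c(-0.4458, 2.819), N9  = c(0.01508, 1.725),
  N10 = c(-1.9500, 0),     N11 = c(-0.3239, 2.202), N12 = c(-1.1190, 0),
  N13 = c(-0.3396, 0.2604), N14 = c(0.2887, 3.359), NS  = c(-0.4806, 2.134),
  O1  = c(0.1552, 1.080),  O2  = c(-0.2893, 0.8238), O3  = c(-0.0684, 1.085),
  O4  = c(-0.4195, 1.182), O5  = c(0.0335, 3.367),  O6  = c(-0.3339, 0.7774),
  O7  = c(-1.1890, 0),     O8  = c(0.1788, 3.135),  O9  = c(-0.1526, 0),
  O10 = c(0.1129, 0.2215), O11 = c(0.4833, 0.389),  O12 = c(-1.3260, 0),
  OS  = c(-0.1188, 0.6865),
  F   = c(0.4202, 1.108),  Cl  = c(0.6895, 5.853),  Br  = c(0.8456, 8.927),
  I   = c(0.8857, 14.02),  Hal = c(-2.9960, 0),
  P   = c(0.8612, 6.920),
  S1  = c(0.6482, 7.591),  S2  = c(-0.0024, 7.365), S3  = c(0.6237, 6.691),
  Me1 = c(-0.3808, 5.754), Me2 = c(-0.0025, 0))

.hetero_set <- c("N", "O", "P", "S", "F", "Cl", "Br", "I")

# per-atom context used by the typing rules
crippen_context <- function(m) {
  n <- n_atoms(m)
  adj <- adjacency_list(m)
  a <- m$atoms; b <- m$bonds
  lapply(seq_len(n), function(i) {
    nb <- adj[[i]]
    if (is.null(nb)) nb <- matrix(integer(), ncol = 2)
    js <- nb[, 1]
    es <- nb[, 2]
    list(
      el = a$element[i], arom = a$aromatic[i], nh = a$n_h[i],
      charge = a$charge[i],
      x = length(js) + a$n_h[i],                       # total connections
      nbr_el = a$element[js], nbr_arom = a$aromatic[js],
      bond_order = if (length(es)) b$order[es] else integer(),
      bond_arom = if (length(es)) b$aromatic[es] else logical())
  })
}

# neighbours of ctx over single (non-aromatic order 1) bonds etc.
.sel <- function(ctx, order = NULL, aromatic_bond = NULL) {
  keep <- rep(TRUE, length(ctx$nbr_el))
  if (!is.null(order)) keep <- keep & ctx$bond_order == order & !ctx$bond_arom
  if (!is.null(aromatic_bond)) keep <- keep & ctx$bond_arom == aromatic_bond
  keep
}

crippen_type_c <- function(ctx, ctxs, js) {
  nbr_el <- ctx$nbr_el; nbr_ar <- ctx$nbr_arom
  ali_C <- nbr_el == "C" & !nbr_ar
  ali_het <- nbr_el %in% .hetero_set & !nbr_ar
  ali <- !nbr_ar
  dbl <- ctx$bond_order == 2L & !ctx$bond_arom
  trp <- ctx$bond_order == 3L & !ctx$bond_arom
  sgl <- ctx$bond_order == 1L & !ctx$bond_arom
  nhv <- length(nbr_el)
  if (!ctx$arom) {
    sp3 <- !any(dbl | trp | ctx$bond_arom)
    # C1/C2: saturated, carbon/hydrogen environment only
    if (sp3 && ctx$nh == 4L && nhv == 0L) return("C1")
    if (sp3 && ctx$nh == 3L && nhv == 1L && all(ali_C)) return("C1")
    if (sp3 && ctx$nh == 2L && nhv == 2L && all(ali_C)) return("C1")
    if (sp3 && ctx$nh == 1L && nhv == 3L && all(ali_C)) return("C2")
    if (sp3 && ctx$nh == 0L && nhv == 4L && all(ali_C)) return("C2")
    # C3/C4: saturated carbon attached to heteroatom(s)
    if (sp3 && ctx$nh == 3L && nhv == 1L && all(ali_het)) return("C3")
    if (sp3 && ctx$nh == 2L && ctx$x == 4L && any(ali_het) && all(ali)) return("C3")
    if (sp3 && ctx$nh == 1L && ctx$x == 4L && any(ali_het) && all(ali)) return("C4")
    if (sp3 && ctx$nh == 0L && ctx$x == 4L && any(ali_het) && all(ali)) return("C4")
    # C5: double bond to an aliphatic heteroatom (carbonyl, imine, ...)
    if (any(dbl & nbr_el != "C" & !nbr_ar)) return("C5")
    # C6: vinylic carbon in an aliphatic environment
    if (ctx$nh == 2L && any(dbl & ali_C)) return("C6")
    if (ctx$nh == 1L && any(dbl & ali_C) && all(ali)) return("C6")
    if (ctx$nh == 0L && sum(dbl & ali_C) == 1L && all(ali) &&
        !any(trp)) return("C6")
    if (sum(dbl & ali_C) == 2L) return("C6")
    # C7: sp carbon
    if (ctx$x == 2L && any(trp & ali)) return("C7")
    # C8-C12: saturated carbon attached to aromatic rings
    if (ctx$nh == 3L && nhv == 1L && all(nbr_el == "C" & nbr_ar)) return("C8")
    if (ctx$nh == 3L && nhv == 1L && all(nbr_ar)) return("C9")
    if (sp3 && ctx$nh == 2L && ctx$x == 4L && any(nbr_ar)) return("C10")
    if (sp3 && ctx$nh == 1L && ctx$x == 4L && any(nbr_ar)) return("C11")
    if (sp3 && ctx$nh == 0L && ctx$x == 4L && any(nbr_ar)) return("C12")
    # C26: conjugated sp2 carbon touching an aromatic system
    if (any(dbl & ali_C) && any(nbr_ar) && ctx$nh == 0L) return("C26")
    if (ctx$nh == 1L && any(dbl & ali_C) && any(nbr_ar)) return("C26")
    if (any(dbl & nbr_el == "C" & nbr_ar)) return("C26")
    # C27: sp3 carbon attached to unusual aliphatic atom (Si, Se, ...)
    if (ctx$x == 4L && !any(dbl | trp) &&
        any(!nbr_ar & !(nbr_el %in% c("C", .hetero_set)))) return("C27")
    return("CS")
  }
  # aromatic carbon
  single_nbrs <- which(sgl)
  if (ctx$nh == 0L && length(single_nbrs) &&
      any(!nbr_ar[single_nbrs] &
          !(nbr_el[single_nbrs] %in% c("C", "N", "O", "S", "F", "Cl", "Br", "I")))) {
    return("C13")
  }
  if (any(nbr_el == "F" & sgl)) return("C14")
  if (any(nbr_el == "Cl" & sgl)) return("C15")
  if (any(nbr_el == "Br" & sgl)) return("C16")
  if (any(nbr_el == "I" & sgl)) return("C17")
  if (ctx$nh == 1L) return("C18")
  n_arom_bonds <- sum(ctx$bond_arom)
  if (n_arom_bonds >= 3L) return("C19")
  if (any(sgl & nbr_ar)) return("C20")
  if (any(sgl & nbr_el == "C" & !nbr_ar)) return("C21")
  if (any(sgl & nbr_el == "N" & !nbr_ar)) return("C22")
  if (any(sgl & nbr_el == "O" & !nbr_ar)) return("C23")
  if (any(sgl & nbr_el == "S" & !nbr_ar)) return("C24")
  if (any(dbl & nbr_el %in% c("C", "N", "O"))) return("C25")
  "CS"
}

crippen_type_n <- function(ctx) {
  nbr_ar <- ctx$nbr_arom
  ali <- !nbr_ar
  dbl <- ctx$bond_order == 2L & !ctx$bond_arom
  trp <- ctx$bond_order == 3L & !ctx$bond_arom
  nhv <- length(ctx$nbr_el)
  ch <- ctx$charge
  if (ctx$arom) {
    if (ch == 0L) return("N11")
    if (ch > 0L) return("N12")
    return("N14")
  }
  if (ch == 0L) {
    if (ctx$nh == 2L && nhv == 1L && ali[1L]) return("N1")
    if (ctx$nh == 1L && nhv == 2L && all(ali) && !any(dbl | trp)) return("N2")
    if (ctx$nh == 2L && nhv == 1L && nbr_ar[1L]) return("N3")
    if (ctx$nh == 1L && nhv == 2L && any(nbr_ar)) return("N4")
    if (ctx$nh == 1L && any(dbl)) return("N5")
    if (ctx$nh == 0L && sum(dbl) == 1L && nhv == 2L) return("N6")
    if (ctx$nh == 0L && nhv == 3L && all(ali) && !any(dbl | trp)) return("N7")
    if (ctx$nh == 0L && nhv == 3L && any(nbr_ar)) return("N8")
    if (any(trp)) return("N9")
    return("NS")
  }
  if (ch > 0L) {
    if (ctx$nh >= 1L) return("N10")
    if (nhv == 4L && !any(dbl | trp)) return("N13")
    if (sum(dbl) == 1L && nhv == 3L) return("N13")
    if (sum(dbl) == 2L) return("N13")
    if (any(trp)) return("N14")
    return("NS")
  }
  "N14"  # anionic nitrogen
}

crippen_type_o <- function(ctx, ctxs, js) {
  nbr_el <- ctx$nbr_el; nbr_ar <- ctx$nbr_arom
  dbl <- ctx$bond_order == 2L & !ctx$bond_arom
  nhv <- length(nbr_el)
  if (ctx$arom) return("O1")
  if (ctx$nh >= 1L && ctx$charge == 0L) return("O2")
  if (ctx$charge == 0L && nhv == 2L && !any(dbl)) {
    if (all(!nbr_ar)) return("O3")
    return("O4")
  }
  # single double-bond partner (carbonyl-family) or charged oxygen
  j <- if (any(dbl)) js[which(dbl)[1L]] else NA_integer_
  pel <- if (!is.na(j)) ctx$nbr_el[which(dbl)[1L]] else NA_character_
  par <- if (!is.na(j)) ctx$nbr_arom[which(dbl)[1L]] else NA
  if (!is.na(j) && pel %in% c("N", "O") && !par) return("O5")
  if (ctx$charge < 0L && nhv == 1L && nbr_el[1L] == "N") return("O5")
  if (ctx$charge < 0L && nhv == 1L && nbr_el[1L] == "S") return("O6")
  if (!is.na(j) && pel == "S" && !par) return("O6")
  if (ctx$charge < 0L && nhv == 1L && nbr_el[1L] == "C") {
    pc <- ctxs[[js[1L]]]
    if (any(pc$bond_order == 2L & !pc$bond_arom & pc$nbr_el == "O")) {
      return("O12")  # carboxylate
    }
  }
  if (ctx$charge < 0L) return("O7")
  if (!is.na(j) && pel == "C" && par) return("O8")
  if (!is.na(j) && pel == "C") {
    pc <- ctxs[[j]]
    # partners of the carbonyl carbon other than this oxygen
    keep <- !(pc$bond_order == 2L & !pc$bond_arom & pc$nbr_el == "O")
    oel <- pc$nbr_el[keep]; oar <- pc$nbr_arom[keep]
    if (any(oar)) return("O10")                         # aryl carbonyl
    if (length(oel) == 2L && all(oel != "C")) return("O11")  # urea/carbonate
    return("O9")                                        # aliphatic carbonyl
  }
  "OS"
}

crippen_type_h_on <- function(parent_ctx, ctxs, parent_idx, adj_js) {
  el <- parent_ctx$el
  if (el == "C" || el == "H") return("H1")
  if (el == "N") return("H3")
  if (el != "O") return("H2")           # S-H, P-H, B-H, ...
  # hydroxyl hydrogen: inspect the oxygen's heavy neighbour
  if (!length(parent_ctx$nbr_el)) return("HS")  # water
  nel <- parent_ctx$nbr_el[1L]; nar <- parent_ctx$nbr_arom[1L]
  j <- adj_js[1L]
  if (nel == "C") {
    cctx <- ctxs[[j]]
    if (nar) return("H2")               # phenol
    if (cctx$x == 4L &&
        !any(cctx$bond_order >= 2L & !cctx$bond_arom)) return("H2")  # alcohol
    if (any(cctx$bond_order == 2L & !cctx$bond_arom &
            cctx$nbr_el %in% c("C", "N", "O", "S"))) return("H4")
    return("HS")
  }
  if (!(nel %in% c("C", "N", "O", "S"))) return("H2")
  if (nel == "N") return("H3")
  if (nel %in% c("O", "S")) return("H4")
  "HS"
}

crippen_type_s <- function(ctx) {
  if (ctx$arom) return("S3")
  if (ctx$charge != 0L) return("S2")
  dbl <- ctx$bond_order == 2L & !ctx$bond_arom
  if (any(dbl & ctx$nbr_el %in% c("N", "O", "P", "S"))) return("S2")
  "S1"
}

#' Wildman-Crippen atomic contributions
#'
#' Assigns each heavy atom one published atom type and returns its logP and
#' molar-refractivity contributions, plus the summed contributions of its
#' implicit hydrogens (typed from the parent atom). Untypeable atoms fall
#' back to the published wildcard class for their element with a warning.
#'
#' @param m a [mol_graph()].
#' @return data.frame with columns `type`, `slogp`, `smr` (heavy atom) and
#'   `h_slogp`, `h_smr` (implicit-hydrogen sums).
#' @export
crippen_contributions <- function(m) {
  ctxs <- crippen_context(m)
  adj <- adjacency_list(m)
  n <- n_atoms(m)
  types <- character(n)
  for (i in seq_len(n)) {
    ctx <- ctxs[[i]]
    js <- if (is.null(adj[[i]])) integer() else adj[[i]][, 1]
    types[i] <- switch(ctx$el,
      C = crippen_type_c(ctx, ctxs, js),
      H = "H1",
      N = crippen_type_n(ctx),
      O = crippen_type_o(ctx, ctxs, js),
      F = if (ctx$charge == 0L) "F" else "Hal",
      Cl = if (ctx$charge == 0L) "Cl" else "Hal",
      Br = if (ctx$charge == 0L) "Br" else "Hal",
      I = if (ctx$charge == 0L) "I" else "Hal",
      P = "P",
      S = crippen_type_s(ctx),
      { warning(sprintf("atom %d (%s) not in the published type table; %s",
                        i, ctx$el, "using metal wildcard"))
        "Me1" })
  }
  vals <- do.call(rbind, .crippen_values[types])
  h_types <- vapply(seq_len(n), function(i) {
    if (m$atoms$n_h[i] == 0L) return(NA_character_)
    js <- if (is.null(adj[[i]])) integer() else adj[[i]][, 1]
    crippen_type_h_on(ctxs[[i]], ctxs, i, js)
  }, "")
  hv <- t(vapply(seq_len(n), function(i) {
    if (is.na(h_types[i])) return(c(0, 0))
    m$atoms$n_h[i] * .crippen_values[[h_types[i]]]
  }, c(0, 0)))
  data.frame(type = types, slogp = vals[, 1], smr = vals[, 2],
             h_slogp = hv[, 1], h_smr = hv[, 2])
}

#' Crippen logP and molar refractivity of a molecule
#'
#' Sum of the Wildman-Crippen atomic contributions including implicit
#' hydrogens.
#'
#' @param m a [mol_graph()].
#' @return Named numeric vector `c(logp = ..., mr = ...)`.
#' @export
crippen_logp <- function(m) {
  ct <- crippen_contributions(m)
  c(logp = sum(ct$slogp) + sum(ct$h_slogp),
    mr = sum(ct$smr) + sum(ct$h_smr))
}
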