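# SMILES reader/writer for the hydrogen-suppressed molecular graph.
# Covers the standard organic subset, bracket atoms (charge, explicit H,
# tetrahedral parity), branches, ring closures (incl. %nn), aromatic
# lowercase forms, and directional single bonds (/ \, accepted and treated
# as single bonds: double-bond geometry is not retained on the graph).

.organic_subset <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.aromatic_ok <- c("B", "C", "N", "O", "P", "S")
.default_valence <- list(B = 3, C = 4, N = 3, O = 2, P = c(3, 5),
                         S = c(2, 4, 6), F = 1, Cl = 1, Br = 1, I = 1)

smiles_error <- function(pos, msg) {
  stop(sprintf("SMILES parse error at position %d: %s", pos, msg),
       call. = FALSE)
}

#' Parse a SMILES string into a molecular graph
#'
#' Builds a [mol_graph()] with perceived aromaticity and implicit-hydrogen
#' counts. Aromatic lowercase input is honoured directly; Kekule input is
#' aromatized by a Huckel-style ring perception pass (5- and 6-membered
#' rings with six pi electrons). Directional bond marks (`/`, `\`) are
#' accepted but double-bond geometry is not represented on the graph;
#' tetrahedral parity marks (`@`, `@@`) are kept as atom stereo tags.
#'
#' @param smiles a single SMILES string.
#' @param name optional molecule name.
#' @return A [mol_graph()].
#' @examples
#' parse_structure("c1ccccc1", name = "benzene")
#' @export
parse_structure <- function(smiles, name = "") {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles)) {
    stop("smiles must be a single string")
  }
  chars <- strsplit(smiles, "")[[1]]
  nc <- length(chars)
  if (nc == 0L) smiles_error(1L, "empty SMILES")

  atoms <- list()
  bonds <- list()
  prev <- NA_integer_          # atom awaiting the next bond
  pend_order <- NA_integer_    # explicit bond symbol pending
  stack <- integer()           # branch stack
  rings <- list()              # open ring closures: num -> c(atom, order, pos)
  i <- 1L

  add_atom <- function(element, aromatic, charge = 0L, n_h = NA_integer_,
                       stereo = "unspecified", bracket = FALSE, pos = i) {
    atoms[[length(atoms) + 1L]] <<- list(
      element = element, charge = charge, n_h = n_h, aromatic = aromatic,
      stereo = stereo, bracket = bracket)
    idx <- length(atoms)
    if (!is.na(prev)) {
      ord <- pend_order
      if (is.na(ord)) {
        ord <- if (atoms[[prev]]$aromatic && aromatic) 0L else 1L # 0 = aromatic
      }
      bonds[[length(bonds) + 1L]] <<- c(prev, idx, ord)
    }
    pend_order <<- NA_integer_
    prev <<- idx
    invisible(idx)
  }

  read_bracket <- function() {
    start <- i
    i <<- i + 1L
    # optional isotope (ignored beyond parsing)
    while (i <= nc && chars[i] %in% as.character(0:9)) i <<- i + 1L
    if (i > nc) smiles_error(start, "unterminated bracket atom")
    sym <- chars[i]
    aromatic <- sym %in% letters
    if (i < nc && chars[i + 1L] %in% letters &&
        paste0(toupper(sym), chars[i + 1L]) %in%
          c("Cl", "Br", "Si", "Se", "As", "Na", "Li", "Mg", "Ca", "Zn", "Fe")) {
      sym <- paste0(toupper(sym), chars[i + 1L])
      i <<- i + 1L
      aromatic <- FALSE
    } else {
      sym <- if (aromatic) toupper(sym) else sym
    }
    if (!grepl("^[A-Z][a-z]?$", sym)) smiles_error(i, "unknown element symbol")
    i <<- i + 1L
    stereo <- "unspecified"
    n_h <- 0L
    charge <- 0L
    while (i <= nc && chars[i] != "]") {
      ch <- chars[i]
      if (ch == "@") {
        if (i < nc && chars[i + 1L] == "@") { stereo <- "@@"; i <<- i + 2L }
        else { stereo <- "@"; i <<- i + 1L }
      } else if (ch == "H") {
        i <<- i + 1L
        n_h <- 1L
        if (i <= nc && chars[i] %in% as.character(0:9)) {
          n_h <- as.integer(chars[i]); i <<- i + 1L
        }
      } else if (ch %in% c("+", "-")) {
        sgn <- if (ch == "+") 1L else -1L
        i <<- i + 1L
        mag <- 1L
        if (i <= nc && chars[i] %in% as.character(0:9)) {
          mag <- as.integer(chars[i]); i <<- i + 1L
        } else {
          while (i <= nc && chars[i] == ch) { mag <- mag + 1L; i <<- i + 1L }
        }
        charge <- sgn * mag
      } else {
        smiles_error(i, sprintf("unexpected character '%s' in bracket atom", ch))
      }
    }
    if (i > nc) smiles_error(start, "unterminated bracket atom")
    i <<- i + 1L  # skip ']'
    add_atom(sym, aromatic, charge = charge, n_h = n_h, stereo = stereo,
             bracket = TRUE, pos = start)
  }

  ring_closure <- function(num, pos) {
    if (is.na(prev)) smiles_error(pos, "ring closure before any atom")
    key <- as.character(num)
    if (!is.null(rings[[key]])) {
      open <- rings[[key]]
      ord <- pend_order
      if (is.na(ord)) ord <- open[2L]
      if (is.na(ord)) {
        ord <- if (atoms[[open[1L]]]$aromatic && atoms[[prev]]$aromatic) 0L else 1L
      }
      if (open[1L] == prev) smiles_error(pos, "ring bond to the same atom")
      bonds[[length(bonds) + 1L]] <<- c(open[1L], prev, ord)
      rings[[key]] <<- NULL
    } else {
      rings[[key]] <- c(prev, pend_order, pos)
      rings[[key]] <<- c(prev, pend_order, pos)
    }
    pend_order <<- NA_integer_
  }

  while (i <= nc) {
    ch <- chars[i]
    if (ch %in% c("C", "B") && i < nc && chars[i + 1L] %in% c("l", "r") &&
        paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      add_atom(paste0(ch, chars[i + 1L]), FALSE); i <- i + 2L
    } else if (ch %in% .organic_subset) {
      add_atom(ch, FALSE); i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      add_atom(toupper(ch), TRUE); i <- i + 1L
    } else if (ch == "[") {
      read_bracket()
    } else if (ch %in% as.character(0:9)) {
      ring_closure(as.integer(ch), i); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > nc || !all(chars[i + 1:2] %in% as.character(0:9))) {
        smiles_error(i, "'%' must be followed by two digits")
      }
      ring_closure(as.integer(paste0(chars[i + 1L], chars[i + 2L])), i)
      i <- i + 3L
    } else if (ch == "-") { pend_order <- 1L; i <- i + 1L
    } else if (ch == "=") { pend_order <- 2L; i <- i + 1L
    } else if (ch == "#") { pend_order <- 3L; i <- i + 1L
    } else if (ch == ":") { pend_order <- 0L; i <- i + 1L
    } else if (ch %in% c("/", "\\")) { pend_order <- 1L; i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) smiles_error(i, "branch start before any atom")
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) smiles_error(i, "unmatched ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == ".") {
      prev <- NA_integer_; pend_order <- NA_integer_; i <- i + 1L
    } else if (ch %in% c(" ", "\t")) {
      if (!nzchar(name)) name <- trimws(paste(chars[i:nc], collapse = ""))
      break
    } else {
      smiles_error(i, sprintf("unexpected character '%s'", ch))
    }
  }
  if (length(stack)) smiles_error(nc, "unclosed branch '('")
  if (length(rings)) {
    open <- rings[[1L]]
    smiles_error(open[3L], "unclosed ring bond")
  }
  if (!length(atoms)) smiles_error(1L, "no atoms found")

  atom_df <- data.frame(
    element = vapply(atoms, `[[`, "", "element"),
    charge = vapply(atoms, function(a) as.integer(a$charge), 0L),
    n_h = vapply(atoms, function(a) as.integer(a$n_h), 0L),
    aromatic = vapply(atoms, `[[`, TRUE, "aromatic"),
    stereo = vapply(atoms, `[[`, "", "stereo"),
    stringsAsFactors = FALSE)
  bracket <- vapply(atoms, `[[`, TRUE, "bracket")
  bond_df <- if (length(bonds)) {
    bm <- do.call(rbind, bonds)
    data.frame(a1 = bm[, 1], a2 = bm[, 2],
               order = ifelse(bm[, 3] == 0L, 1L, bm[, 3]),
               aromatic = bm[, 3] == 0L)
  } else {
    data.frame(a1 = integer(), a2 = integer(), order = integer(),
               aromatic = logical())
  }
  bad <- which(atom_df$aromatic & !(atom_df$element %in% .aromatic_ok))
  if (length(bad)) {
    smiles_error(1L, sprintf("element '%s' cannot be aromatic",
                             atom_df$element[bad[1L]]))
  }

  # demote aromatic bonds that are not in any ring (e.g. biphenyl linkage)
  if (nrow(bond_df) && any(bond_df$aromatic)) {
    inring <- bonds_in_ring(atom_df, bond_df)
    demote <- bond_df$aromatic & !inring
    bond_df$aromatic[demote] <- FALSE
    bond_df$order[demote] <- 1L
  }

  atom_df$n_h <- assign_implicit_h(atom_df, bond_df, bracket)
  m <- mol_graph(atom_df, bond_df, name = name)
  perceive_aromaticity(m)
}

# is each bond part of a cycle? (removing it keeps its endpoints connected)
bonds_in_ring <- function(atom_df, bond_df) {
  g <- igraph::graph_from_data_frame(
    bond_df[, c("a1", "a2")], directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(atom_df))))
  vapply(seq_len(nrow(bond_df)), function(k) {
    g2 <- igraph::delete_edges(g, k)
    d <- igraph::distances(g2, v = as.character(bond_df$a1[k]),
                           to = as.character(bond_df$a2[k]))
    is.finite(d[1, 1])
  }, TRUE)
}

assign_implicit_h <- function(atom_df, bond_df, bracket) {
  n <- nrow(atom_df)
  used <- numeric(n)
  arom_deg <- integer(n)
  if (nrow(bond_df)) {
    for (k in seq_len(nrow(bond_df))) {
      o <- if (bond_df$aromatic[k]) 1 else bond_df$order[k]
      used[bond_df$a1[k]] <- used[bond_df$a1[k]] + o
      used[bond_df$a2[k]] <- used[bond_df$a2[k]] + o
      if (bond_df$aromatic[k]) {
        arom_deg[bond_df$a1[k]] <- arom_deg[bond_df$a1[k]] + 1L
        arom_deg[bond_df$a2[k]] <- arom_deg[bond_df$a2[k]] + 1L
      }
    }
  }
  n_h <- atom_df$n_h
  for (i in seq_len(n)) {
    if (bracket[i]) next  # explicit H count from the bracket
    el <- atom_df$element[i]
    val <- .default_valence[[el]]
    if (is.null(val)) { n_h[i] <- 0L; next }
    u <- used[i]
    # one bonding slot is consumed by the delocalized pi system
    if (atom_df$aromatic[i]) u <- u + 1
    if (el %in% c("N", "O", "P", "S")) val <- val + atom_df$charge[i]
    val <- val[val >= u]
    n_h[i] <- if (length(val)) as.integer(min(val) - u) else 0L
  }
  n_h
}

# Huckel-style perception on Kekule input: mark 5/6-rings with 6 pi
# electrons aromatic. An exocyclic double bond disqualifies its ring atom;
# N/O/S with only single bonds donate a lone pair (2 electrons).
perceive_aromaticity <- function(m) {
  b <- m$bonds
  if (!nrow(b)) return(m)
  rings <- find_rings(m, max_size = 6L)
  if (!length(rings)) return(m)
  dbl_partner <- vector("list", n_atoms(m))
  for (k in seq_len(nrow(b))) {
    if (b$order[k] == 2L && !b$aromatic[k]) {
      dbl_partner[[b$a1[k]]] <- c(dbl_partner[[b$a1[k]]], b$a2[k])
      dbl_partner[[b$a2[k]]] <- c(dbl_partner[[b$a2[k]]], b$a1[k])
    }
  }
  bond_key <- paste(pmin(b$a1, b$a2), pmax(b$a1, b$a2))
  for (ring in rings) {
    if (all(m$atoms$aromatic[ring])) next
    pi_e <- 0L
    ok <- TRUE
    for (a in ring) {
      el <- m$atoms$element[a]
      partners <- dbl_partner[[a]]
      if (length(partners) && any(partners %in% ring)) {
        pi_e <- pi_e + 1L
      } else if (length(partners)) {
        ok <- FALSE; break       # exocyclic double bond (e.g. quinone C=O)
      } else if (m$atoms$aromatic[a]) {
        pi_e <- pi_e + 1L        # fused edge already aromatized
      } else if (el %in% c("N", "O", "S")) {
        pi_e <- pi_e + 2L        # lone-pair donor
      } else if (el == "C" && m$atoms$charge[a] == -1L) {
        pi_e <- pi_e + 2L
      } else { ok <- FALSE; break }
    }
    if (ok && pi_e == 6L) {
      m$atoms$aromatic[ring] <- TRUE
      pairs <- cbind(ring, c(ring[-1L], ring[1L]))
      keys <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
      sel <- bond_key %in% keys
      m$bonds$aromatic[sel] <- TRUE
      m$bonds$order[sel] <- 1L
    }
  }
  validate_mol_graph(m)
  m
}

# simple cycles up to max_size, as ordered atom vectors (each ring once)
find_rings <- function(m, max_size = 6L) {
  adj <- lapply(seq_len(n_atoms(m)), function(i) integer())
  b <- m$bonds
  for (k in seq_len(nrow(b))) {
    adj[[b$a1[k]]] <- c(adj[[b$a1[k]]], b$a2[k])
    adj[[b$a2[k]]] <- c(adj[[b$a2[k]]], b$a1[k])
  }
  out <- list()
  seen <- character()
  path <- integer(max_size)
  dfs <- function(start, v, depth) {
    path[depth] <<- v
    for (w in adj[[v]]) {
      if (w == start && depth >= 3L) {
        ring <- path[seq_len(depth)]
        key <- paste(sort(ring), collapse = ",")
        if (!(key %in% seen)) { seen <<- c(seen, key); out[[length(out) + 1L]] <<- ring }
      } else if (depth < max_size && !(w %in% path[seq_len(depth)]) && w > start) {
        dfs(start, w, depth + 1L)
      }
    }
  }
  for (s in seq_len(n_atoms(m))) dfs(s, s, 1L)
  out
}

#' Read a SMILES file (one molecule per line, optional name)
#'
#' @param path file with one SMILES per line; anything after the first
#'   whitespace is taken as the molecule name. Blank lines and lines
#'   starting with `#` are skipped.
#' @return A list of [mol_graph()] objects.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, parse_structure)
}

#' Read an SDF (MDL V2000) file
#'
#' Parses the atom and bond blocks of each record; charges are taken from
#' `M  CHG` lines. Bond type 4 is read as aromatic; Kekule records are
#' aromatized by the same perception pass as [parse_structure()].
#'
#' @param path SDF file path.
#' @return A list of [mol_graph()] objects.
#' @export
read_sdf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- split(lines, cumsum(c(TRUE, lines[-length(lines)] == "$$$$")))
  out <- list()
  for (rec in recs) {
    rec <- rec[rec != "$$$$"]
    if (length(rec) < 4L) next
    counts <- rec[4L]
    na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
    nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
    if (is.na(na) || is.na(nb)) next
    atom_lines <- rec[4L + seq_len(na)]
    bond_lines <- rec[4L + na + seq_len(nb)]
    els <- trimws(substr(atom_lines, 32, 34))
    a1 <- as.integer(substr(bond_lines, 1, 3))
    a2 <- as.integer(substr(bond_lines, 4, 6))
    bt <- as.integer(substr(bond_lines, 7, 9))
    charge <- integer(na)
    for (ln in rec[startsWith(rec, "M  CHG")]) {
      flds <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]])
      nset <- flds[1L]
      for (j in seq_len(nset)) {
        charge[flds[2 * j]] <- flds[2 * j + 1L]
      }
    }
    atom_df <- data.frame(element = els, charge = charge, n_h = 0L,
                          aromatic = FALSE, stereo = "unspecified",
                          stringsAsFactors = FALSE)
    bond_df <- data.frame(a1 = a1, a2 = a2,
                          order = ifelse(bt == 4L, 1L, bt),
                          aromatic = bt == 4L)
    atom_df$aromatic[unique(c(bond_df$a1[bond_df$aromatic],
                              bond_df$a2[bond_df$aromatic]))] <- TRUE
    atom_df$n_h <- assign_implicit_h(atom_df, bond_df, rep(FALSE, na))
    m <- perceive_aromaticity(mol_graph(atom_df, bond_df, name = trimws(rec[1L])))
    out[[length(out) + 1L]] <- m
  }
  out
}

# --- writer ---------------------------------------------------------------

# iterative-refinement (Morgan-style) canonical ranks; deterministic and
# independent of input atom order up to true graph symmetry
canonical_ranks <- function(m) {
  a <- m$atoms
  inv <- paste(a$element, a$charge, a$n_h, a$aromatic, a$stereo,
               vapply(seq_len(n_atoms(m)), function(i)
                 sum(m$bonds$a1 == i | m$bonds$a2 == i), 0))
  rank <- as.integer(factor(inv, levels = sort(unique(inv))))
  adj <- adjacency_list(m)
  repeat {
    sig <- vapply(seq_len(n_atoms(m)), function(i) {
      nb <- adj[[i]]
      if (is.null(nb)) return(sprintf("%06d", rank[i]))
      nbr <- sort(sprintf("%06d:%d%d", rank[nb[, 1]],
                          m$bonds$order[nb[, 2]], m$bonds$aromatic[nb[, 2]]))
      paste(sprintf("%06d", rank[i]), paste(nbr, collapse = "|"))
    }, "")
    new_rank <- as.integer(factor(sig, levels = sort(unique(sig))))
    if (length(unique(new_rank)) == length(unique(rank))) break
    rank <- new_rank
  }
  rank
}

#' Write a molecular graph as a SMILES string
#'
#' Deterministic writer: atom order is chosen by canonical (iterative
#' refinement) ranks, so isomorphic graphs with permuted atom input order
#' yield the same string. Tetrahedral parity tags are re-emitted;
#' double-bond geometry is not (it is not represented on the graph).
#'
#' @param m a [mol_graph()].
#' @return A single SMILES string.
#' @export
write_smiles <- function(m) {
  n <- n_atoms(m)
  if (n == 0L) stop("empty molecule")
  rank <- canonical_ranks(m)
  adj <- adjacency_list(m)
  visited <- logical(n)
  # pre-pass: find ring-closure bonds via DFS
  tree_edge <- rep(FALSE, nrow(m$bonds))
  comp_roots <- integer()
  ord <- order(rank, seq_len(n))
  dfs_mark <- function(v) {
    visited[v] <<- TRUE
    nb <- adj[[v]]
    if (is.null(nb)) return()
    for (r in order(rank[nb[, 1]], nb[, 1])) {
      w <- nb[r, 1]; e <- nb[r, 2]
      if (!visited[w]) { tree_edge[e] <<- TRUE; dfs_mark(w) }
    }
  }
  for (v in ord) if (!visited[v]) { comp_roots <- c(comp_roots, v); dfs_mark(v) }
  # ring-closure digits are allocated in emission order (and reused once
  # closed) so the written string is canonical for a given traversal
  open_digit <- list()   # bond index -> digit
  used_digits <- logical(99)
  next_digit <- function() {
    d <- which(!used_digits)[1L]
    used_digits[d] <<- TRUE
    d
  }

  bond_sym <- function(e) {
    if (m$bonds$aromatic[e]) return("")
    switch(m$bonds$order[e], "", "=", "#")
  }
  atom_token <- function(i) {
    a <- m$atoms[i, ]
    el <- a$element
    sym <- if (a$aromatic) tolower(el) else el
    plain_ok <- el %in% .organic_subset && a$charge == 0L &&
      a$stereo == "unspecified" && (!a$aromatic || el %in% .aromatic_ok)
    if (plain_ok) {
      # check the reader would infer the same H count
      tmp_used <- 0
      nb <- adj[[i]]
      if (!is.null(nb)) {
        for (r in seq_len(nrow(nb))) {
          tmp_used <- tmp_used +
            if (m$bonds$aromatic[nb[r, 2]]) 1 else m$bonds$order[nb[r, 2]]
        }
      }
      if (a$aromatic) tmp_used <- tmp_used + 1
      val <- .default_valence[[el]]
      val <- val[val >= tmp_used]
      inferred <- if (length(val)) min(val) - tmp_used else 0
      if (inferred == a$n_h) return(sym)
    }
    stereo <- if (a$stereo %in% c("@", "@@")) a$stereo else
      if (a$stereo == "S") "@" else if (a$stereo == "R") "@@" else ""
    hpart <- if (a$n_h == 1L) "H" else if (a$n_h > 1L) paste0("H", a$n_h) else ""
    cpart <- if (a$charge > 0L) {
      if (a$charge == 1L) "+" else paste0("+", a$charge)
    } else if (a$charge < 0L) {
      if (a$charge == -1L) "-" else paste0("-", abs(a$charge))
    } else ""
    paste0("[", sym, stereo, hpart, cpart, "]")
  }

  visited2 <- logical(n)
  emit <- function(v, from_edge) {
    parts <- atom_token(v)
    visited2[v] <<- TRUE
    nb <- adj[[v]]
    if (!is.null(nb)) {
      # ring closure digits on this atom, in canonical neighbour order
      for (r in order(rank[nb[, 1]], nb[, 1])) {
        e <- nb[r, 2]
        if (tree_edge[e]) next
        key <- as.character(e)
        if (is.null(open_digit[[key]])) {
          d <- next_digit()
          open_digit[[key]] <<- d
        } else {
          d <- open_digit[[key]]
          open_digit[[key]] <<- NULL
          used_digits[d] <<- FALSE
        }
        dig <- if (d < 10L) as.character(d) else sprintf("%%%02d", d)
        parts <- paste0(parts, bond_sym(e), dig)
      }
      children <- nb[order(rank[nb[, 1]], nb[, 1]), , drop = FALSE]
      kids <- list()
      for (r in seq_len(nrow(children))) {
        w <- children[r, 1]; e <- children[r, 2]
        if (tree_edge[e] && !visited2[w]) {
          kids[[length(kids) + 1L]] <- paste0(bond_sym(e), emit(w, e))
        }
      }
      if (length(kids) > 1L) {
        for (k in seq_len(length(kids) - 1L)) {
          parts <- paste0(parts, "(", kids[[k]], ")")
        }
      }
      if (length(kids)) parts <- paste0(parts, kids[[length(kids)]])
    }
    parts
  }
  paste(vapply(comp_roots, function(v) emit(v, NA), ""), collapse = ".")
}
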