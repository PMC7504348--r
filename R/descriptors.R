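# Descriptor-vector assembly: exactly the named 2D descriptors appearing
# in the two published linear pIC50 models.

.ache_descriptor_names <- c("BCUT_SLOGP_3", "reactive", "PEOE_VSA+1",
                            "PEOE_VSA-3", "SlogP_VSA2", "SMR_VSA2")
.bace1_descriptor_names <- c("petitjean", "BCUT_PEOE_1", "a_ICM", "chiral_u",
                             "rings", "a_Nn", "PEOE_VSA-0", "PEOE_VSA-6",
                             "logS", "SlogP_VSA3", "SlogP_VSA5")

#' Descriptor names used by the published models
#'
#' @param set `"ache"`, `"bace1"` or `"all"`.
#' @return Character vector of descriptor names.
#' @export
descriptor_names <- function(set = c("all", "ache", "bace1")) {
  set <- match.arg(set)
  switch(set,
    ache = .ache_descriptor_names,
    bace1 = .bace1_descriptor_names,
    all = union(.ache_descriptor_names, .bace1_descriptor_names))
}

# the source tables write a_Nn; the conventional program name is a_nN
normalize_descriptor_name <- function(x) {
  x[x == "a_nN"] <- "a_Nn"
  x
}

#' Compute a named descriptor vector for one molecule
#'
#' Deterministic and independent of atom input order. Supported names are
#' those of [descriptor_names()] plus the full `PEOE_VSA`, `SlogP_VSA` and
#' `SMR_VSA` families.
#'
#' @param m a [mol_graph()].
#' @param names descriptor names to compute (default: all model terms).
#' @param config see [vsa_config()].
#' @param reactive_list pattern list for the `reactive` term, see
#'   [reactive_patterns()].
#' @return Named numeric vector in the requested order.
#' @export
descriptor_vector <- function(m, names = descriptor_names("all"),
                              config = vsa_config(),
                              reactive_list = reactive_patterns()) {
  names <- normalize_descriptor_name(names)
  charges <- NULL; contribs <- NULL
  peoe_prof <- NULL; slogp_prof <- NULL; smr_prof <- NULL
  need_charges <- function() {
    if (is.null(charges)) charges <<- peoe_charges(m)
    charges
  }
  need_contribs <- function() {
    if (is.null(contribs)) contribs <<- crippen_contributions(m)
    contribs
  }
  get_profile <- function(family) {
    switch(family,
      peoe = {
        if (is.null(peoe_prof)) {
          peoe_prof <<- peoe_vsa_profile(m, need_charges(), config)
        }
        peoe_prof
      },
      slogp = {
        if (is.null(slogp_prof)) {
          slogp_prof <<- slogp_vsa_profile(m, need_contribs(), config)
        }
        slogp_prof
      },
      smr = {
        if (is.null(smr_prof)) {
          smr_prof <<- smr_vsa_profile(m, need_contribs(), config)
        }
        smr_prof
      })
  }
  counts <- NULL
  need_counts <- function() {
    if (is.null(counts)) counts <<- simple_counts(m)
    counts
  }
  one <- function(nm) {
    if (startsWith(nm, "PEOE_VSA")) {
      prof <- get_profile("peoe")
      if (!nm %in% names(prof)) stop_unknown(nm)
      return(prof[[nm]])
    }
    if (startsWith(nm, "SlogP_VSA")) {
      prof <- get_profile("slogp")
      if (!nm %in% names(prof)) stop_unknown(nm)
      return(prof[[nm]])
    }
    if (startsWith(nm, "SMR_VSA")) {
      prof <- get_profile("smr")
      if (!nm %in% names(prof)) stop_unknown(nm)
      return(prof[[nm]])
    }
    switch(nm,
      BCUT_SLOGP_0 = bcut(m, "SLOGP", 0L, diag = need_contribs()$slogp),
      BCUT_SLOGP_1 = bcut(m, "SLOGP", 1L, diag = need_contribs()$slogp),
      BCUT_SLOGP_2 = bcut(m, "SLOGP", 2L, diag = need_contribs()$slogp),
      BCUT_SLOGP_3 = bcut(m, "SLOGP", 3L, diag = need_contribs()$slogp),
      BCUT_PEOE_0 = bcut(m, "PEOE", 0L, diag = as.numeric(need_charges())),
      BCUT_PEOE_1 = bcut(m, "PEOE", 1L, diag = as.numeric(need_charges())),
      BCUT_PEOE_2 = bcut(m, "PEOE", 2L, diag = as.numeric(need_charges())),
      BCUT_PEOE_3 = bcut(m, "PEOE", 3L, diag = as.numeric(need_charges())),
      reactive = as.numeric(reactive_flag(m, reactive_list)),
      petitjean = petitjean_index(m),
      a_ICM = a_icm(m),
      chiral_u = as.numeric(need_counts()[["chiral_u"]]),
      rings = as.numeric(need_counts()[["rings"]]),
      a_Nn = as.numeric(need_counts()[["a_Nn"]]),
      logS = log_solubility(m),
      stop_unknown(nm))
  }
  stop_unknown <- function(nm) {
    stop(sprintf(
      "unsupported descriptor '%s'; supported: %s, PEOE_VSA-6..PEOE_VSA+6, SlogP_VSA0..9, SMR_VSA0..8",
      nm, paste(descriptor_names("all"), collapse = ", ")))
  }
  stats::setNames(vapply(names, one, 0), names)
}

#' Descriptor table for a list of molecules
#'
#' @param mols list of [mol_graph()] objects (optionally named).
#' @param names descriptor names, see [descriptor_vector()].
#' @param ... passed to [descriptor_vector()].
#' @return data.frame with an `id` column followed by one column per
#'   descriptor.
#' @export
descriptor_table <- function(mols, names = descriptor_names("all"), ...) {
  rows <- lapply(mols, descriptor_vector, names = names, ...)
  ids <- names(mols)
  if (is.null(ids)) {
    ids <- vapply(mols, function(m)
      if (nzchar(m$name)) m$name else NA_character_, "")
    ids[is.na(ids)] <- paste0("mol", which(is.na(ids)))
  }
  out <- as.data.frame(do.call(rbind, rows))
  cbind(data.frame(id = ids, stringsAsFactors = FALSE), out,
        row.names = NULL)
}
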