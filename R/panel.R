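# The synthesized-compound panel: 13 N-substituted phenothiazine-chalcones
# (AC1-AC13) plus the reference inhibitors galantamine (AChE), verubecestat
# and quercetin (BACE-1), with observed/predicted activities, docking
# scores and HR-MS m/z as printed. SMILES for AC1-AC13 are derived from
# the systematic names (common scaffold:
# 10-(3-(dimethylamino)propyl)-10H-phenothiazin-2-yl ketone with an
# (E)-configured enone to the substituted B ring); each structure is
# validated against its printed [M+H]+ m/z in the test suite.

.panel_md5 <- "f72547f3ebd1b9167aa0927a17e45458"

#' Load the chalcone panel fixture
#'
#' Returns the versioned 16-record panel (AC1-AC13, galantamine,
#' verubecestat, quercetin) with every printed activity, docking score and
#' HR-MS value. The fixture is stored as a flat CSV inside the package
#' (`system.file("extdata", "panel.csv", package = "chalqsar")`) with a
#' documented column schema, and is checksummed on load.
#'
#' Columns: `id`, `smiles`, `ic50_ache_um(_sd)`, `pic50_ache_obs(_sd)`,
#' `pic50_ache_pred`, the same four for BACE-1, `dock_ache`,
#' `dock_bace_a`, `dock_bace_b` (kJ/mol), `mh_mz` (Da) and `fig5a`
#' (membership in the 9-compound AChE correlation subset AC1-AC3,
#' AC6-AC11).
#'
#' @param path override the packaged fixture path (for testing).
#' @return data.frame with 16 rows.
#' @export
load_chalcone_panel <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "panel.csv", package = "chalqsar")
    if (!nzchar(path)) stop("packaged panel fixture not found")
    sum <- unname(tools::md5sum(path))
    if (!identical(sum, .panel_md5)) {
      stop("panel fixture checksum mismatch: expected ", .panel_md5,
           ", got ", sum)
    }
  }
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "smiles", "ic50_ache_um", "ic50_ache_sd", "pic50_ache_obs",
            "pic50_ache_sd", "pic50_ache_pred", "ic50_bace_um",
            "ic50_bace_sd", "pic50_bace_obs", "pic50_bace_sd",
            "pic50_bace_pred", "dock_ache", "dock_bace_a", "dock_bace_b",
            "mh_mz")
  miss <- setdiff(need, names(p))
  if (length(miss)) {
    stop("panel fixture is missing column(s): ", paste(miss, collapse = ", "))
  }
  p
}

#' Parsed structures for the panel
#'
#' @param panel optionally a pre-loaded [load_chalcone_panel()] table.
#' @return Named list of [mol_graph()] objects.
#' @export
panel_structures <- function(panel = load_chalcone_panel()) {
  mols <- lapply(seq_len(nrow(panel)), function(i)
    parse_structure(panel$smiles[i], name = panel$id[i]))
  stats::setNames(mols, panel$id)
}
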