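# Structure parsing, formulas, masses, and the panel fixture.

test_that("SMILES parsing perceives aromaticity and hydrogens", {
  b <- parse_structure("c1ccccc1")
  expect_equal(nrow(b$atoms), 6L)
  expect_true(all(b$atoms$aromatic))
  expect_true(all(b$bonds$aromatic))
  expect_equal(sum(b$atoms$n_h), 6L)
  expect_equal(unname(simple_counts(b)["rings"]), 1L)

  # Kekule input aromatizes to the same graph
  bk <- parse_structure("C1=CC=CC=C1")
  expect_true(all(bk$atoms$aromatic))
  expect_equal(molecular_formula(bk), "C6H6")

  ac1 <- parse_structure(oracle_ac1_smiles, name = "AC1")
  expect_equal(nrow(ac1$atoms), 30L)
  expect_equal(molecular_formula(ac1), "C26H26N2OS")
  expect_identical(ac1$atoms$element, oracle_ac1_atoms)

  # quinone-type exocyclic C=O must not aromatize its ring
  q <- parse_structure("O=C1C=CC(=O)C=C1")
  expect_false(any(q$atoms$aromatic))
})

test_that("unparsable SMILES raise structured errors naming the position", {
  expect_error(parse_structure("C1CC"), "position 2.*unclosed ring")
  expect_error(parse_structure("C(C"), "unclosed branch")
  expect_error(parse_structure("C$C"), "position 2")
  expect_error(parse_structure("[Xx]"), "SMILES parse error")
  expect_error(peoe_charges(parse_structure("[Se]C")), "not available")
})

test_that("molecular formulas follow Hill order", {
  expect_equal(molecular_formula(parse_structure("C")), "CH4")
  expect_equal(molecular_formula(parse_structure("O")), "H2O")
  expect_equal(molecular_formula(parse_structure("OS(=O)(=O)O")), "H2O4S")
})

test_that("monoisotopic [M+H]+ matches hand-computed values", {
  # 2 x 1.0078250 + 15.9949146 + 1.0072765
  expect_equal(monoisotopic_mh(parse_structure("O")), 19.0184, tolerance = 1e-4)
  expect_error(monoisotopic_mh(mol_graph(data.frame(
    element = "Xe", charge = 0L, n_h = 0L, aromatic = FALSE,
    stereo = "unspecified"))), "isotope mass")
})

test_that("panel fixture has the printed records and activities", {
  p <- load_chalcone_panel()
  expect_equal(nrow(p), 16L)
  expect_equal(sum(grepl("^AC[0-9]+$", p$id)), 13L)
  expect_setequal(setdiff(p$id, paste0("AC", 1:13)),
                  c("Galanthamine", "Verubecestat", "Quercetin"))
  ac12 <- p[p$id == "AC12", ]
  expect_equal(ac12$pic50_ache_obs, 5.96)
  expect_equal(ac12$ic50_ache_um, 1.10)
  gal <- p[p$id == "Galanthamine", ]
  expect_equal(gal$ic50_ache_um, 1.26)
  expect_equal(gal$dock_ache, -28.53)
  ac10 <- p[p$id == "AC10", ]
  expect_equal(c(ac10$dock_bace_a, ac10$dock_bace_b), c(-22.51, -20.81))
  expect_true(all(nzchar(p$smiles)))
})

test_that("every printed IC50/pIC50 pair is internally consistent", {
  p <- load_chalcone_panel()
  for (tgt in c("ache", "bace")) {
    ic <- p[[paste0("ic50_", tgt, "_um")]]
    pc <- p[[paste0("pic50_", tgt, "_obs")]]
    ok <- !is.na(ic) & !is.na(pc)
    expect_true(any(ok))
    expect_true(all(abs(pc[ok] - pic50(ic[ok])) <= 0.02),
                label = paste("IC50/pIC50 consistency for", tgt))
  }
})

test_that("derived structures reproduce the printed HR-MS m/z", {
  p <- load_chalcone_panel()
  mols <- panel_structures(p)
  has_mz <- !is.na(p$mh_mz)
  expect_equal(sum(has_mz), 13L)
  for (i in which(has_mz)) {
    expect_lt(abs(monoisotopic_mh(mols[[p$id[i]]]) - p$mh_mz[i]), 0.01)
  }
})

test_that("parse -> write -> parse round-trips to an isomorphic graph", {
  p <- load_chalcone_panel()
  for (smi in c(p$smiles, "CC(=O)Oc1ccccc1C(=O)O", "C[C@H](N)C(=O)O")) {
    m1 <- parse_structure(smi)
    s <- write_smiles(m1)
    m2 <- parse_structure(s)
    expect_equal(molecular_formula(m2), molecular_formula(m1))
    expect_equal(nrow(m2$bonds), nrow(m1$bonds))
    expect_equal(simple_counts(m2), simple_counts(m1))
    expect_equal(write_smiles(m2), s)  # writer is a fixed point
  }
})

test_that("the canonical writer is independent of atom input order", {
  m <- parse_structure("CC(=O)Oc1ccccc1")
  for (seed in 1:5) {
    perm <- withr::with_seed(seed, sample(nrow(m$atoms)))
    expect_equal(write_smiles(permute_mol(m, perm)), write_smiles(m))
  }
})

test_that("SDF records parse to the same graphs as their SMILES", {
  # minimal V2000 block for ethanol written in code
  sdf <- c("ethanol", "  test", "",
           "  3  2  0  0  0  0  0  0  0  0999 V2000",
           "    0.0000    0.0000    0.0000 C   0  0",
           "    1.0000    0.0000    0.0000 C   0  0",
           "    2.0000    0.0000    0.0000 O   0  0",
           "  1  2  1  0", "  2  3  1  0", "M  END", "$$$$")
  path <- withr::local_tempfile(fileext = ".sdf")
  writeLines(sdf, path)
  mols <- read_sdf(path)
  expect_length(mols, 1L)
  expect_equal(molecular_formula(mols[[1]]), "C2H6O")
  expect_equal(mols[[1]]$name, "ethanol")
})

test_that("mol_graph invariants are enforced", {
  a <- data.frame(element = c("C", "C"), charge = 0L, n_h = 3L,
                  aromatic = FALSE, stereo = "unspecified")
  expect_error(mol_graph(a, data.frame(a1 = 1, a2 = 1, order = 1,
                                       aromatic = FALSE)), "self-bonds")
  expect_error(mol_graph(a, data.frame(a1 = c(1, 2), a2 = c(2, 1),
                                       order = 1, aromatic = FALSE)),
               "duplicate")
  expect_error(mol_graph(a, data.frame(a1 = 1, a2 = 3, order = 1,
                                       aromatic = FALSE)), "valid atoms")
  expect_error(mol_graph(a, data.frame(a1 = 1, a2 = 2, order = 1,
                                       aromatic = TRUE)),
               "aromatic bonds")
})
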