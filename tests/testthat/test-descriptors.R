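# Descriptor layer: PEOE charges, Crippen contributions, VSA binning,
# BCUT, topological and count descriptors, and assembly invariants.

ac1 <- parse_structure(oracle_ac1_smiles, name = "AC1")

test_that("PEOE charges match the independent toolkit oracle", {
  m <- parse_structure("C")
  q <- peoe_charges(m)
  expect_lt(q[1], 0)
  expect_equal(unname(q[1]), oracle_methane_c_peoe, tolerance = 1e-3)
  expect_equal(sum(q) + sum(attr(q, "h_charge")), 0, tolerance = 1e-6)

  qa <- peoe_charges(ac1)
  expect_lt(max(abs(qa - oracle_ac1_peoe)), 2e-3)
})

test_that("PEOE charges conserve total formal charge", {
  amm <- parse_structure("[NH4+]")
  q <- peoe_charges(amm)
  expect_equal(sum(q) + sum(attr(q, "h_charge")), 1, tolerance = 1e-3)

  for (smi in random_smiles(40, seed = 11)) {
    m <- parse_structure(smi)
    q <- peoe_charges(m)
    expect_equal(sum(q) + sum(attr(q, "h_charge")),
                 sum(m$atoms$charge), tolerance = 1e-3,
                 label = paste("charge conservation for", smi))
  }
})

test_that("Crippen contributions reproduce the published table per atom", {
  ct <- crippen_contributions(ac1)
  expect_equal(ct$slogp, oracle_ac1_slogp, tolerance = 1e-6)
  expect_equal(ct$smr, oracle_ac1_smr, tolerance = 1e-6)

  expect_equal(unname(crippen_logp(parse_structure("c1ccccc1"))["logp"]),
               oracle_benzene_logp, tolerance = 1e-4)
  # oxygen lowers logP: ethanol below ethane
  etoh <- unname(crippen_logp(parse_structure("CCO"))["logp"])
  eth <- unname(crippen_logp(parse_structure("CC"))["logp"])
  expect_equal(etoh, oracle_ethanol_logp, tolerance = 1e-4)
  expect_equal(eth, oracle_ethane_logp, tolerance = 1e-4)
  expect_lt(etoh, eth)
  # totality: bare methane carbon gets one finite type
  ct1 <- crippen_contributions(parse_structure("C"))
  expect_true(is.finite(ct1$slogp))
})

test_that("approximate VSA obeys the sphere-and-cap geometry", {
  # isolated atom with no bonds: full sphere 4 pi r^2
  lone <- mol_graph(data.frame(element = "C", charge = 0L, n_h = 0L,
                               aromatic = FALSE, stereo = "unspecified"))
  r <- vsa_config()$vdw_radius[["C"]]
  expect_equal(approximate_vsa(lone), 4 * pi * r^2, tolerance = 1e-12)
  # any bonded atom strictly below the full sphere
  eth <- parse_structure("CC")
  expect_true(all(approximate_vsa(eth) < 4 * pi * r^2))
  # benzene carbons all equal by symmetry
  vb <- approximate_vsa(parse_structure("c1ccccc1"))
  expect_equal(max(vb) - min(vb), 0, tolerance = 1e-12)
  expect_true(all(approximate_vsa(ac1) >= 0))
})

test_that("binned VSA partitions the total area exactly", {
  v <- approximate_vsa(ac1)
  q <- as.numeric(peoe_charges(ac1))
  ct <- crippen_contributions(ac1)
  cfg <- vsa_config()
  for (prof in list(binned_vsa(ac1, q, cfg$peoe_bins, vsa = v),
                    binned_vsa(ac1, ct$slogp, cfg$slogp_bins, vsa = v),
                    binned_vsa(ac1, ct$smr, cfg$smr_bins, vsa = v))) {
    expect_equal(sum(prof), sum(v), tolerance = 1e-6 * sum(v))
  }
  # a single atom lands in exactly one bin
  lone <- mol_graph(data.frame(element = "C", charge = 0L, n_h = 0L,
                               aromatic = FALSE, stereo = "unspecified"))
  b <- binned_vsa(lone, 0.07, c(-0.1, 0, 0.05, 0.1))
  expect_equal(sum(b > 0), 1L)
  expect_gt(b[4], 0)  # 0.07 in (0.05, 0.1]
  expect_error(binned_vsa(lone, 0.07, c(0.1, 0)), "ascending")
})

test_that("PEOE bin membership agrees with the oracle charges", {
  # which atoms fall in which charge bin is dialect-free: check the named
  # bins used by the models against the frozen oracle charges
  q <- as.numeric(peoe_charges(ac1))
  bins <- vsa_config()$peoe_bins
  mine <- findInterval(q, bins, left.open = TRUE)
  orac <- findInterval(oracle_ac1_peoe, bins, left.open = TRUE)
  expect_equal(mine, orac)
})

test_that("Burden eigenvalues have the stated closed forms", {
  lone <- mol_graph(data.frame(element = "C", charge = 0L, n_h = 0L,
                               aromatic = FALSE, stereo = "unspecified"))
  expect_equal(burden_eigenvalues(lone, 0.5), 0.5)
  two <- parse_structure("CC")
  expect_equal(burden_eigenvalues(two, c(0, 0)), c(-0.1, 0.1),
               tolerance = 1e-12)
  # trace identity on an arbitrary molecule
  d <- crippen_contributions(ac1)$slogp
  expect_equal(sum(burden_eigenvalues(ac1, d)), sum(d), tolerance = 1e-9)
})

test_that("BCUT indices are ordered statistics of the spectrum", {
  for (m in list(ac1, parse_structure("CCOC(=O)c1ccccc1"))) {
    vals <- vapply(0:3, function(k) bcut(m, "SLOGP", k), 0)
    expect_true(all(diff(vals) >= -1e-12))
    valp <- vapply(0:3, function(k) bcut(m, "PEOE", k), 0)
    expect_true(all(diff(valp) >= -1e-12))
  }
  lone <- mol_graph(data.frame(element = "C", charge = 0L, n_h = 0L,
                               aromatic = FALSE, stereo = "unspecified"))
  for (k in 0:3) expect_equal(bcut(lone, "SLOGP", k, diag = 0.3), 0.3)
  ac4 <- parse_structure("O=C(/C=C/c1cc(OC)c(OC)c(OC)c1)c1ccc2Sc3ccccc3N(CCCN(C)C)c2c1")
  expect_gt(bcut(ac4, "SLOGP", 3L), 0)
})

test_that("Petitjean index matches hand-computed cases and its bounds", {
  expect_equal(petitjean_index(parse_structure("c1ccccc1")), 0)
  expect_equal(petitjean_index(parse_structure("CCC")), 1)
  lone <- mol_graph(data.frame(element = "C", charge = 0L, n_h = 4L,
                               aromatic = FALSE, stereo = "unspecified"))
  expect_equal(petitjean_index(lone), 0)
  for (seed in 1:20) {
    g <- random_carbon_graph(sample(3:15, 1), extra_edges = seed %% 3,
                             seed = seed)
    p <- petitjean_index(g)
    expect_gte(p, 0); expect_lte(p, 1)
  }
})

test_that("element entropy a_ICM matches closed forms", {
  h2 <- mol_graph(data.frame(element = c("H", "H"), charge = 0L, n_h = 0L,
                             aromatic = FALSE, stereo = "unspecified"),
                  data.frame(a1 = 1, a2 = 2, order = 1, aromatic = FALSE))
  expect_equal(a_icm(h2), 0)
  expect_equal(a_icm(parse_structure("C")), 0.7219, tolerance = 1e-4)
  expect_equal(a_icm(parse_structure("O")), 0.9183, tolerance = 1e-4)
})

test_that("count descriptors match their definitions", {
  expect_equal(unname(simple_counts(parse_structure("c1ccccc1"))),
               c(1L, 0L, 0L))
  sc <- simple_counts(ac1)
  expect_equal(unname(sc["rings"]), 4L)   # three fused + B-ring phenyl
  expect_equal(unname(sc["a_Nn"]), 2L)
  # explicit stereo mark removes the unassigned-centre count
  marked <- parse_structure("[C@H](F)(Cl)Br")
  unmarked <- parse_structure("C(F)(Cl)Br")
  expect_equal(unname(simple_counts(marked)["chiral_u"]), 0L)
  expect_equal(unname(simple_counts(unmarked)["chiral_u"]), 1L)
})

test_that("logS surrogate follows its linear formula", {
  m <- parse_structure("CCO")
  clogp <- unname(crippen_logp(m)["logp"])
  byhand <- 0.16 - 0.63 * clogp - 0.0062 * molecular_weight(m) +
    0.066 * rotatable_bonds(m) - 0.74 * 0
  expect_equal(log_solubility(m), byhand, tolerance = 1e-12)
  # logS decreases as clogP grows along an alkane series, all else similar
  ls <- vapply(c("CCCC", "CCCCCC", "CCCCCCCC"),
               function(s) log_solubility(parse_structure(s)), 0)
  expect_true(all(diff(ls) < 0))
})

test_that("reactive flag follows the configurable pattern list", {
  expect_equal(reactive_flag(parse_structure("CC")), 0L)
  expect_equal(reactive_flag(parse_structure("CC(=O)Cl")), 1L)  # acyl halide
  expect_equal(reactive_flag(parse_structure("C1CO1")), 1L)     # epoxide
  expect_equal(reactive_flag(parse_structure("CN=C=O")), 1L)    # isocyanate
  # enone is excluded by default and detected when enabled
  expect_equal(reactive_flag(ac1), 0L)
  expect_equal(reactive_flag(ac1, reactive_patterns(include_enone = TRUE)),
               1L)
  expect_error(reactive_flag(ac1, list(bad = "not a function")),
               "not a function")
  expect_error(reactive_flag(ac1, list(1, 2)), "named")
})

test_that("descriptor vectors are complete, finite and order-invariant", {
  v <- descriptor_vector(parse_structure("c1ccccc1"),
                         descriptor_names("ache"))
  expect_length(v, 6L)
  expect_true(all(is.finite(v)))
  expect_equal(unname(v["reactive"]), 0)

  full <- descriptor_vector(ac1, descriptor_names("all"))
  for (seed in 1:5) {
    perm <- withr::with_seed(seed, sample(nrow(ac1$atoms)))
    vp <- descriptor_vector(permute_mol(ac1, perm), descriptor_names("all"))
    expect_equal(vp, full, tolerance = 1e-9)
  }
  expect_error(descriptor_vector(ac1, "no_such_descriptor"), "unsupported")
  # the a_nN spelling is accepted
  expect_equal(unname(descriptor_vector(ac1, "a_nN")), 2)
})

test_that("descriptor invariance holds across random molecules", {
  smis <- random_smiles(25, seed = 99)
  for (smi in smis) {
    m <- parse_structure(smi)
    v0 <- descriptor_vector(m, c("petitjean", "a_ICM", "rings", "a_Nn",
                                 "BCUT_SLOGP_3", "SlogP_VSA2"))
    perm <- withr::with_seed(7, sample(nrow(m$atoms)))
    v1 <- descriptor_vector(permute_mol(m, perm),
                            c("petitjean", "a_ICM", "rings", "a_Nn",
                              "BCUT_SLOGP_3", "SlogP_VSA2"))
    expect_equal(v1, v0, tolerance = 1e-9, label = smi)
  }
})
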