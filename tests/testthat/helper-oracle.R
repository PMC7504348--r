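# Frozen expected values computed with an independent cheminformatics
# toolkit (RDKit 2024.09, Gasteiger charges at its default 12 sweeps and
# the published Wildman-Crippen table) on the AC1 structure
# O=C(/C=C/c1ccccc1)c1ccc2Sc3ccccc3N(CCCN(C)C)c2c1.
oracle_ac1_smiles <- "O=C(/C=C/c1ccccc1)c1ccc2Sc3ccccc3N(CCCN(C)C)c2c1"
oracle_ac1_atoms <- c("O", "C", "C", "C", "C", "C", "C", "C", "C", "C", "C",
                      "C", "C", "C", "S", "C", "C", "C", "C", "C", "C", "N",
                      "C", "C", "C", "N", "C", "C", "C", "C")
oracle_ac1_peoe <- c(-0.289289, 0.185429, -0.013397, -0.051086, -0.025529,
                     -0.054983, -0.061672, -0.062226, -0.061672, -0.054983,
                     0.023994, -0.049786, -0.045382, 0.036050, -0.085708,
                     0.036002, -0.046118, -0.060989, -0.060114, -0.037236,
                     0.055236, -0.339574, 0.024356, -0.022278, -0.000784,
                     -0.309332, -0.013694, -0.013694, 0.055978, -0.026047)
oracle_ac1_slogp <- c(0.11290, -0.27830, 0.15510, 0.26400, 0.13600, 0.15810,
                      0.15810, 0.15810, 0.15810, 0.15810, 0.13600, 0.15810,
                      0.15810, 0.18930, 0.64820, 0.18930, 0.15810, 0.15810,
                      0.15810, 0.15810, 0.46190, -0.44580, -0.20350, 0.14410,
                      -0.20350, -0.31870, -0.20350, -0.20350, 0.46190,
                      0.15810)
oracle_ac1_smr <- c(0.22150, 5.00700, 3.51300, 4.30500, 3.50900, 3.35000,
                    3.35000, 3.35000, 3.35000, 3.35000, 3.50900, 3.35000,
                    3.35000, 2.67300, 7.59100, 2.67300, 3.35000, 3.35000,
                    3.35000, 3.35000, 4.06700, 2.81900, 2.75300, 2.50300,
                    2.75300, 1.83900, 2.75300, 2.75300, 4.06700, 3.35000)
oracle_methane_c_peoe <- -0.077558    # rdkit Gasteiger, "C"
oracle_benzene_logp <- 1.6866         # 6 x C18 (0.1581) + 6 x H1 (0.1230)
oracle_ethanol_logp <- -0.0014        # rdkit MolLogP("CCO")
oracle_ethane_logp <- 1.0262          # rdkit MolLogP("CC")
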