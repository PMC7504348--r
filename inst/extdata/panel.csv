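id,smiles,ic50_ache_um,ic50_ache_sd,pic50_ache_obs,pic50_ache_sd,pic50_ache_pred,ic50_bace_um,ic50_bace_sd,pic50_bace_obs,pic50_bace_sd,pic50_bace_pred,dock_ache,dock_bace_a,dock_bace_b,mh_mz,fig5a
AC1,O=C(/C=C/c1ccccc1)c1ccc2Sc3ccccc3N(CCCN(C)C)c2c1,33.88,1.45,4.47,0.02,4.80,6.34,0.46,5.20,0.03,6.52,-25.83,-17.82,-17.69,415.1814,TRUE
AC2,O=C(/C=C/c1cccc(OC)c1)c1ccc2Sc3ccccc3N(CCCN(C)C)c2c1,30.90,2.10,4.51,0.03,4.74,3.00,0.00,5.52,0.00,7.38,-26.03,-17.22,-17.81,445.1977,TRUE
AC3,O=C(/C=C/c1ccc(OC)cc1)c1ccc2Sc3ccccc3N(CCCN(C)C)c2c1,11.48,1.29,4.94,0.05,4.74,4.48,0.40,5.35,0.04,7.37,-27.67,-16.28,-15.37,445.1923,TRUE
AC4,O=C(/C=C/c1cc(OC)c(OC)c(OC)c1)c1ccc2Sc3ccccc3N(CCCN(C)C)c2c1,3.63,0.61,5.44,0.08,4.71,0.16,0.03,6.81,0.09,8.49,-24.49,-16.71,-13.92,505.2132,FALSE
AC5,O=C(/C=C/c1ccc(Cl)cc1)c1ccc2Sc3ccccc3N(CCCN(C)C)c2c1,60.26,1.84,4.22,0.01,4.82,1.24,0.12,5.91,0.04,7.25,-17.71,-20.77,-16.87,449.1451,FALSE
AC6,O=C(/C=C/c1ccc(Cl)cc1Cl)c1ccc2Sc3ccccc3N(CCCN(C)C)c2c1,19.95,1.57,4.70,0.03,4.83,0.50,0.00,6.30,0.00,7.68,-25.45,-18.79,-16.73,483.1054,TRUE
AC7,O=C(/C=C/c1c(Cl)cccc1F)c1ccc2Sc3ccccc3N(CCCN(C)C)c2c1,40.74,2.48,4.39,0.03,4.76,0.45,0.04,6.35,0.04,7.63,-17.94,-19.51,-16.85,467.1368,TRUE
AC8,O=C(/C=C/c1ccccc1Cl)c1ccc2Sc3ccccc3N(CCCN(C)C)c2c1,15.85,1.08,4.80,0.03,4.82,2.97,0.05,5.53,0.01,7.15,-26.27,-20.36,-16.81,449.1475,TRUE
AC9,O=C(/C=C/c1ccc(F)cc1)c1ccc2Sc3ccccc3N(CCCN(C)C)c2c1,25.12,0.83,4.60,0.01,4.76,3.72,0.21,5.43,0.02,7.12,-27.80,-20.97,-18.06,433.1754,TRUE
AC10,O=C(/C=C/c1cccc(Br)c1)c1ccc2Sc3ccccc3N(CCCN(C)C)c2c1,24.55,1.09,4.61,0.02,4.81,1.99,0.21,5.70,0.05,7.28,-27.30,-22.51,-20.81,493.0949,TRUE
AC11,O=C(/C=C/c1ccccc1C(F)(F)F)c1ccc2Sc3ccccc3N(CCCN(C)C)c2c1,186.21,4.52,3.73,0.01,4.59,0.40,0.00,6.40,0.00,7.99,-25.33,-19.35,-16.41,483.1721,TRUE
AC12,O=C(/C=C/c1ccc(N(C)C)cc1)c1ccc2Sc3ccccc3N(CCCN(C)C)c2c1,1.10,0.24,5.96,0.10,4.81,0.35,0.04,6.46,0.05,8.08,-22.15,-18.25,-16.18,458.2298,FALSE
AC13,O=C(/C=C/c1ccc(OCc2ccccc2)cc1)c1ccc2Sc3ccccc3N(CCCN(C)C)c2c1,11.75,0.63,4.93,0.02,4.63,3.03,0.21,5.52,0.03,7.20,-23.30,-11.50,-14.09,521.2243,FALSE
Galanthamine,CN1CC[C@@]23C=C[C@@H](O)C[C@@H]2Oc2c(OC)ccc(C1)c23,1.26,0.12,5.90,0.04,5.14,NA,NA,NA,NA,NA,-28.53,NA,NA,NA,FALSE
Verubecestat,CC1(c2cc(NC(=O)c3ccc(F)cn3)ccc2F)CS(=O)(=O)N(C)C(N)=N1,NA,NA,NA,NA,NA,NA,NA,NA,NA,7.66,NA,-24.95,-22.43,NA,FALSE
Quercetin,O=C1C(O)=C(c2ccc(O)c(O)c2)Oc2cc(O)cc(O)c12,NA,NA,NA,NA,NA,9.55,0.37,5.02,0.02,5.24,NA,-22.23,-23.95,NA,FALSE
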