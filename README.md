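# chalqsar

2D-QSAR modelling of N-substituted phenothiazine-chalcone inhibitors of
acetylcholinesterase (AChE) and beta-secretase (BACE-1), for
cheminformaticians and medicinal chemists who want the complete
computational pipeline behind this class of study in plain R: descriptor
calculation from first principles, the published linear activity models,
PLS model building with the full external-validation metric suite, and
the enzyme-assay arithmetic from plate absorbances to pIC50.

## What it computes

The package centres on two linear pIC50 models over named 2D descriptors,

```
pIC50(AChE)   = -0.928 + 2.348 BCUT_SLOGP_3 - 0.150 reactive - 0.004 PEOE_VSA+1
                - 0.005 PEOE_VSA-3 - 0.002 SlogP_VSA2 - 0.004 SMR_VSA2
pIC50(BACE-1) =  1.268 + 0.870 petitjean + 6.370 BCUT_PEOE_1 + 3.305 a_ICM
                - 0.478 chiral_u + 0.085 rings + 0.157 a_Nn + 0.006 PEOE_VSA-0
                + 0.022 PEOE_VSA-6 - 0.260 logS + 0.009 SlogP_VSA3 + 0.009 SlogP_VSA5
```

and implements every term on a molecular graph parsed from SMILES:
Gasteiger PEOE partial charges, Wildman-Crippen logP/MR atomic
contributions, the subdivided van der Waals surface-area families
(PEOE_VSA / SlogP_VSA / SMR_VSA), Burden-matrix BCUT eigenvalue
descriptors, the Petitjean shape index, element-entropy and count
descriptors, an ESOL-style logS surrogate and a configurable
reactive-group flag. Around the models it provides NIPALS PLS with
leave-one-out component selection, the validation metrics
(RMSE, R2 in both trendline and residual forms, Q2_LOO, R2_PRED, the Roy
rm2 family, Lin's CCC), the randomized 70/30 split, Ellman-assay percent
inhibition with log-linear IC50 extrapolation
(pIC50 = 6 - log10(IC50/uM)), and seeded synthetic-data generators. The
13-compound chalcone panel plus reference inhibitors ships as a
checksummed CSV fixture with all printed activities, docking scores and
HR-MS masses.

## Worked example

```r
library(chalqsar)

panel <- load_chalcone_panel()
ache  <- run_pipeline(panel, "AChE", subset_fig5a = TRUE)
ache
#> <pipeline_report> AChE: 16 compounds, observed-vs-predicted R2 = 0.30 (n = 9)
round(ache$correlation_printed$r2, 2)
#> [1] 0.62

bace <- run_pipeline(panel, "BACE-1")
round(bace$correlation_printed$r2, 2)
#> [1] 0.83

pic50(1.26)          # galantamine, IC50 1.26 uM
#> [1] 5.899629

m <- parse_structure(panel$smiles[panel$id == "AC12"], name = "AC12")
monoisotopic_mh(m)   # printed HR-MS m/z: 458.2298
#> [1] 458.2261
descriptor_vector(m, descriptor_names("ache"))[1:2]
#> BCUT_SLOGP_3     reactive 
#>    0.7092167    0.0000000
```

`correlation_printed` is the squared Pearson correlation between the
panel's observed pIC50 and the printed model predictions -- 0.62 over
the 9-compound AChE subset (AC1-AC3, AC6-AC11) and 0.83 over all 13
chalcones for BACE-1. `correlation` is the same quantity computed with
this package's own descriptor dialect; absolute predictions depend on
the descriptor program's conventions (see the methods vignette), which
is why the two differ. The `analysis/` scripts run the full study in
order: panel integrity checks, descriptor tables, predictions and
correlations, a synthetic PLS validation study with a y-scrambling
control, and assay-recovery curves, each writing its tables under
`results/`.

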