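Package: chalqsar
Title: 2D-QSAR Modelling of Phenothiazine-Chalcone Cholinesterase and
    Beta-Secretase Inhibitors
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for 2D quantitative structure-activity relationship
    (QSAR) analysis of chalcone-type acetylcholinesterase (AChE) and
    beta-secretase (BACE-1) inhibitors. Implements the molecular graph
    substrate and the 2D descriptors used by the published linear pIC50
    models (PEOE partial-charge VSA bins, Crippen SlogP/SMR VSA bins,
    Burden-matrix BCUT eigenvalue descriptors, Petitjean shape index,
    element-entropy and count descriptors, an ESOL-style log-solubility
    surrogate and a reactive-group flag), the two published linear
    descriptor models, partial-least-squares model building with the
    full external-validation metric suite (Q2 leave-one-out, rm2 family,
    concordance correlation), Ellman-assay percent-inhibition and
    log-linear IC50 extrapolation arithmetic, and seeded synthetic-data
    generators for end-to-end testing. Ships the 13-compound
    N-substituted phenothiazine-chalcone panel with reference compounds
    as a versioned fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
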