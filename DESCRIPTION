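Package: crosscell
Title: Cross-Cell-Type Translation of Cardiac Drug Responses from
    Simulated Myocyte Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates heterogeneous populations of cardiac myocyte models
    (an adult-ventricular-like and a spontaneously beating iPSC-like
    fixture cell are included), extracts action-potential and calcium
    transient biomarkers under a panel of pacing and extracellular-ion
    protocols, and fits partial least squares regression models that
    translate drug-induced physiological changes from one cell type to
    another. Includes PRESS-based cross-validated component selection,
    greedy and exhaustive ranking of experimental protocols by predictive
    information, and an in silico pharmacology layer representing drugs as
    concentration-dependent pore block of ion transport pathways.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
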