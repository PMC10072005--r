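Package: motornet
Title: Resting-State fNIRS Motor-Network Connectivity, Small-World
    Metrics and Dyskinesia Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for resting-state near-infrared
    spectroscopy (fNIRS) recordings of the motor cortex: motion-artifact
    detection and spline correction, band-pass filtering, common average
    referencing, Fisher-Z functional connectivity with proportional
    thresholding, small-world graph metrics normalized against
    degree-preserving random references, threshold-AUC features,
    covariate-adjusted group statistics with FDR control, partial
    correlation with clinical motor scores, and nested cross-validated
    one-versus-rest linear support vector machine classification of
    dyskinesia degree. Includes a seeded synthetic-cohort generator with
    group-dependent latent network topology for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    MASS,
    signal,
    zoo,
    e1071,
    emmeans,
    jsonlite,
    yaml,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
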