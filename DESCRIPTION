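Package: netquant
Title: High-Content Image Analysis of Neutrophil Extracellular Trap Formation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A high-content screening pipeline for quantifying NETosis (lytic
    neutrophil extracellular trap formation) from multi-channel fluorescence
    microscopy plates. Provides a seeded synthetic-plate simulator with ground
    truth, nuclear segmentation of the Hoechst channel including grossly
    enlarged NETotic chromatin, a multiparametric per-cell feature set
    (morphology, intensity, density, Haralick/GLCM, Gabor and spots/edges/
    ridges texture), a regularized linear-discriminant phenotype classifier
    with a lytic gate, and screen-level analytics: percent-NETotic well
    summaries, Z-prime plate QC, hit calling, four-parameter logistic EC50
    fits, ROS and TMRM kinetic summaries, and ANOVA with Monte-Carlo Dunnett
    comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    jsonlite,
    minpack.lm,
    nnet,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
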