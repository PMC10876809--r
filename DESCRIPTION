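Package: longimets
Title: Longitudinal Detection, Matching and Volumetric Quantification of
    Brain Metastases in Paired MRI Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the longitudinal analysis of contrast-enhancing brain
    metastases in paired prior/current T1-weighted gadolinium MRI volumes.
    Implements the full pipeline: brain region-of-interest extraction, rigid
    inter-scan registration, simultaneous multi-channel 3D U-Net lesion
    segmentation (one-, two- and three-channel variants), connected-component
    lesion extraction with sphere-equivalent diameter stratification, a
    bipartite lesion-matching graph with change classification (existing, new,
    disappeared) and volumetric change quantification, together with the
    evaluation metrics (size-stratified detection precision/recall, Dice,
    average symmetric surface distance, matching-edge and change-class
    precision/recall) and a seeded synthetic longitudinal phantom generator
    that makes every stage testable without clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    oro.nifti,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
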