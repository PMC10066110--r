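Package: vamorph
Title: Vestibular Aqueduct Morphometry from Volumetric CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for measuring the vestibular aqueduct (VA) on volumetric
    CT: Hounsfield-band threshold segmentation with seeded component
    selection and plane clipping, centerline-based 2D diameter measurement
    at the anatomical midpoint and operculum, VA volumetry by voxel counting
    and watertight surface meshing, classification of enlarged vestibular
    aqueduct (EVA) by the Cincinnati, Valvassori and volumetric criteria,
    and the accompanying nonparametric statistical battery (Kruskal-Wallis
    with Dunn post hoc, Spearman correlation, ICC(2,1), ROC with Youden
    cutoff, Clopper-Pearson intervals, Hodges-Lehmann differences).
    Includes a synthetic temporal-bone phantom generator with analytic
    ground truth for validating every stage, cohort simulation calibrated
    to published group-wise diameter distributions, and a study pipeline
    with simulated blinded raters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
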