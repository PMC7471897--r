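Package: nodulord
Title: Ordinal Invasiveness Models for Subsolid Lung Nodules from CT
    Attenuation and Geometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Three-class invasiveness analysis for subsolid lung nodules on
    computed tomography. Computes first-order geometric and attenuation
    (Hounsfield-unit histogram) features from segmented nodules, represents
    per-nodule attenuation densities in log-quantile-density space and
    summarizes them by functional principal components, screens candidate
    predictors by ROC-AUC at both ordinal cutoffs, fits cumulative-logit
    proportional-odds models with simulation-based effect interpretation,
    and assesses discrimination and calibration by repeated stratified
    Monte-Carlo cross-validation. Includes a synthetic nodule cohort
    generator so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC,
    optparse
Config/testthat/edition: 3
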