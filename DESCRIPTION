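Package: csfpanels
Title: CSF Biomarker Panel Discovery and Prognosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Discovery and evaluation of cerebrospinal-fluid (CSF) biomarker
    panels for early-stage dementia. Implements the full analysis pipeline for
    wide multiplex-immunoassay cohorts: quality control with detection-limit
    and outlier imputation, Box-Cox driven transform selection, covariate
    adjusted univariate screening, binormal optimal-linear-combination ROC
    panel construction with bootstrap evaluation, a model-agnostic repeated
    train/test resampling harness with native nearest-shrunken-centroid,
    naive Bayes and k-nearest-neighbour reference classifiers, and staged Cox
    proportional-hazards selection of prognostic panels. A latent-factor
    synthetic cohort generator with ground-truth records makes every stage
    testable without access to restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    emmeans,
    randomForest
Config/testthat/edition: 3
RoxygenNote: 7.3.3
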