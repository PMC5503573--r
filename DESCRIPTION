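Package: metabscreen
Title: Marker Screening and Classification for Untargeted Urine Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable implementation of a case-control marker-discovery
    workflow for untargeted LC-MS feature tables: synthetic two-group cohort
    simulation with zero-inflated log-normal ion intensities, a four-stage
    candidate-ion screening cascade (detection frequency, Gaussian-fitted log
    fold-change thresholding, Wilcoxon rank-sum filtering, ROC AUC filtering),
    OPLS-DA and locally linear embedding for separation assessment, gain-ratio
    (C4.5-style) decision-tree classification, and a stratified
    cross-validation plus independent-test evaluation protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    pROC,
    vegan,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
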