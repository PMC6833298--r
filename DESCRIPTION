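Package: silacqc
Title: Quality Control of SILAC Peptide Spectra with Imbalance-Aware
    Boosted Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spectrum-level quality control for SILAC (stable isotope
    labeling by amino acids in cell culture) quantitative proteomics.
    Computes thirteen quality features from isotope-cluster observations
    (mass deviation, preceding-peak ratio, signal-to-noise, isotope
    pattern deviations for the light and heavy clusters, and scan isotope
    pattern deviations across neighboring LC scans), auto-tags training
    data from quantitative-ratio and mass-deviation rules, re-balances
    the minority class with SMOTE, trains a gradient boosted tree quality
    classifier with an optional Gaussian-process hyperparameter search,
    and evaluates filtering quality through a log-scale coefficient of
    variation, with protein-level aggregation. A synthetic-data generator
    with known ground-truth quality labels makes the full pipeline
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    e1071,
    pROC,
    stats,
    utils,
    xgboost
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
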