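Package: sepclust
Title: Unsupervised Clustering for Sepsis Identification in ICU Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end pipeline for identifying sepsis phenotypes in ICU
    hospitalization data without a priori labels. Generates synthetic
    EHR-like cohorts with planted cluster structure, builds and reduces a
    high-dimensional feature matrix (Kaiser-Meyer-Olkin filtering followed
    by principal component analysis), benches eight clustering algorithms
    including a from-scratch Robust and Sparse K-means, selects the best
    algorithm by internal-validity rank aggregation and subsampling
    stability, assigns external-cohort patients to clusters with a tuned
    gradient-boosted tree model, and analyzes clusters against a
    configurable CDC Adult Sepsis Event (ASE) criteria engine including
    liberalized-threshold variants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    cluster,
    mclust,
    xgboost,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
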