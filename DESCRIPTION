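Package: pathdose
Title: Pathway Activity Inference for Dose-Structured Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis workflow for detecting coordinated pathway-level
    transcriptional responses across ionizing-radiation dose levels. Implements
    a probabilistic pathway activity inference scheme based on per-gene
    Gaussian log-likelihood ratios with moment normalization and aggregated
    t-statistic scoring, dose-structured experiments (per-dose contrasts,
    progressive low-dose inclusion, top-k ranked-list intersection, dose
    profiles of fitted models), and a pathway-constrained variational
    autoencoder with a masked linear decoder and Monte-Carlo Bayes-factor
    differential activity testing. A synthetic-data generator emulating a
    multi-donor, seven-dose blood irradiation study design makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    jsonlite,
    uwot
Suggests:
    testthat (>= 3.0.0),
    cluster
Config/testthat/edition: 3
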