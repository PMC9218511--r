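Package: ggmtox
Title: Toxicity Category Prediction from Gene Partial-Correlation Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts chemical toxicity categories from the transcriptional
    response of pluripotent stem cells. Dose-response viability curves are
    fitted with a three-parameter log-logistic model to set exposure doses;
    RNA-seq counts are filtered, normalised to logCPM, batch-corrected and
    summarised as per-chemical, per-dose log fold changes; a 20-gene feature
    panel is selected from principal-component loadings; per-chemical sparse
    Gaussian graphical models are estimated by L1 graphical lasso with BIC
    penalty selection; and the 190 partial-correlation edge weights feed
    leave-one-out support-vector-machine classifiers with per-fold t-test
    feature ranking, including a transductive transfer mode that predicts
    unlabeled second-cell-line data and a uniform-random baseline
    significance test. A synthetic-data generator emulates the full
    24-chemical, 6-dose, 2-replicate, 2-timepoint design with known ground
    truth so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    e1071,
    igraph,
    minpack.lm,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    edgeR,
    limma,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
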