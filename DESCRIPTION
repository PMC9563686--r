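Package: agescan
Title: Aberrant Gene Expression Detection from RNA-Seq Counts Without
    Replicates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects aberrant gene expression (AGE) in RNA-seq count
    matrices without replicates or a control group. A variational
    autoencoder reconstructs the count matrix; two reconstruction-fidelity
    scores (a standardized count-ratio divergence score and a log2 delta
    count) are computed per (gene, sample) point; per-gene linear
    regression influence diagnostics (standardized residuals, DFBETAS,
    leverage, Cook's distance) feed a CART decision tree whose extracted
    interval rules classify points as aberrant or normal; an isolation
    forest ranks calls by an anomaly score. Includes a negative-binomial
    cohort simulator with covariate structure, the semi-synthetic
    aberration-injection model used to train and benchmark the classifier,
    and precision/recall benchmarking utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    rpart,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    optparse
Config/testthat/edition: 3
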