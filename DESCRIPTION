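Package: dcmimpute
Title: Missing-Node Imputation and Model Selection for fMRI Dynamic Causal Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates BOLD fMRI cohorts from bilinear neural dynamics coupled
    to balloon-Windkessel hemodynamics, treats task-network nodes that fail a
    first-level activation test as missing data, imputes their time series by
    zero-, mean-, noise- or EM-Gaussian filling, inverts candidate dynamic
    causal models with a variational Laplace scheme to obtain free-energy log
    model evidence, and evaluates subject classification by highest evidence
    together with RMSE, mutual-information and k-means clustering diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
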