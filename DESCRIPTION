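Package: tfnbs
Title: Threshold-Free Network-Based Statistics for Structural Brain Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Group comparison of white-matter structural connectivity matrices
    using threshold-free network-based statistics (TFNBS). Provides empirical-Bayes
    batch harmonization (ComBat-style location/scale adjustment preserving group,
    age and sex effects), edge-wise general linear models with nuisance covariates,
    threshold-free cluster enhancement over graph components, permutation-based
    family-wise-error-corrected and uncorrected p-value graphs, and lobe-pair
    summaries of significant connections. Includes a synthetic-cohort generator
    emulating sparse symmetric connectomes with covariate and scanner-batch
    effects and a planted group-difference subnetwork, so the whole pipeline is
    testable without MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    sva,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
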