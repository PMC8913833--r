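Package: metabnet
Title: Dynamic Metabolic Covariance Networks from Longitudinal MRS Concentrations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and compares metabolic covariance networks from longitudinal
    proton MRS metabolite concentration tables (LCModel-style output). Provides
    CRLB-based quality filtering, per-time-point absolute Spearman correlation
    networks over a threshold sweep, sign-test backbone extraction, efficiency-based
    small-worldness against degree-preserving random ensembles, and permutation
    group tests on threshold-AUC summaries with FDR correction. Includes a
    Gaussian-copula synthetic-cohort generator with prescribed rank-correlation
    structure for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
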