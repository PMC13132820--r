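Package: splscv
Title: Sparse Partial Least Squares Signatures with Nested Cross-Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-block sparse partial least squares (SPLS) for clinical
    signature discovery: l1/l2-constrained latent-variable extraction by
    alternating soft-thresholded power iterations, stratified nested
    cross-validation with in-fold standardization and optional covariate
    residualization, permutation-based latent-variable significance,
    projection deflation for successive components, and bootstrap-ratio
    feature stability with Procrustes alignment. Includes the univariate
    cohort statistics that typically accompany such analyses
    (tie-corrected Kruskal-Wallis, Pearson chi-square, Spearman
    correlation, Benjamini-Hochberg FDR) and a synthetic-cohort generator
    with a planted low-rank cross-block covariance and deterministic
    abstinence-outcome couplings, so the full pipeline is testable
    without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
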