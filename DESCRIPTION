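Package: toplineGS
Title: Top-Line Selection for Genomic Prediction via Threshold Classification
    and Cutoff Optimization
Version: 0.1.0
Authors@R: person("Topline", "Maintainers", email = "maintainers@toplinegs.org",
    role = c("aut", "cre"))
Description: Tools for selecting top candidate lines in genomic selection
    programs. Implements the conventional GBLUP regression classifier, its
    reformulation as a Bayesian probit threshold (liability) classifier, and a
    postprocessing step that rescales the decision threshold on continuous
    GBLUP predictions to balance sensitivity and specificity. Includes marker
    quality control, the VanRaden genomic relationship matrix, a nested
    (outer/inner) cross-validation harness with decision-cutoff tuning, a
    binary classification metric suite (Cohen's kappa, F1, sensitivity,
    specificity, relative efficiency), and a synthetic genotype/phenotype
    simulator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    S4Vectors
Config/testthat/edition: 3
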