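Package: gpbench
Title: Genome-Enabled Prediction Models and Cross-Validation Benchmarking
Version: 0.1.0
Authors@R: person("gpbench", "developers", role = c("aut", "cre"),
    email = "gpbench@example.org")
Description: Whole-genome regression and non-parametric models for
    genome-enabled prediction of quantitative traits from dense binary
    (dominant, DArT-style) markers: Bayesian ridge regression, the Bayesian
    LASSO, Bayes A and Bayes B Gibbs samplers; reproducing kernel Hilbert
    space (RKHS) regression with Gaussian kernels and kernel averaging;
    radial basis function networks trained by orthogonal least-squares
    center selection; and Bayesian-regularized single-hidden-layer networks
    trained by the evidence framework. Includes a synthetic-data generator
    for additive and epistatic genetic architectures with target
    heritability, a replicated random-partition cross-validation driver
    with Pearson correlation and predictive mean-squared-error metrics,
    paired significance testing, and broad-sense heritability calculators.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
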