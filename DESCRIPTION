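Package: BayesMTGP
Title: Bayesian Multi-Trait and Multi-Environment Genomic Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Bayesian whole-genome regression models for multi-trait and
    multi-trait multi-environment plant breeding data. Implements a blocked
    Gibbs sampler for matrix-variate normal line effects with unstructured
    trait, environment and residual covariance matrices (GBLUP
    parameterisation through a VanRaden genomic relationship matrix and
    Cholesky whitening), a univariate Bayesian regression engine (Bayesian
    ridge regression and BayesB), two-stage multi-output regressor stacking,
    random and K-fold cross-validation schemes for incomplete field trials,
    and prediction-accuracy summaries based on Pearson correlation and the
    mean arctangent absolute percentage error (MAAPE). A synthetic-data
    generator draws phenotypes from the same generative model so all
    functionality is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
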