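Package: twinsem
Title: Biometric Structural Equation Models for Longitudinal Twin Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for etiological analysis of longitudinal twin-pair data:
    simulation of twin panels with additive-genetic and non-shared
    environmental structure, one-factor measurement models with cross-wave
    loading-equality constraints and regression factor scores, chained-equation
    imputation, phenotypic and double-entry cross-twin correlations,
    multivariate Cholesky ACE/AE variance decomposition, and a genetically
    informative random-intercept cross-lagged panel model (RI-CLPM), all
    estimated by two-group full-information maximum likelihood with compiled
    likelihood kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
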