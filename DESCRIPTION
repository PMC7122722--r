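Package: ardlfire
Title: Dynamic Simulated ARDL Models for Fire-Climate Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the relationship between monthly grassland area burned
    and climate drivers with autoregressive distributed lag (ARDL) models in
    error-correction form. Provides unit-root classification (augmented
    Dickey-Fuller and Phillips-Perron tests with embedded finite-sample
    critical values), VAR lag-order selection, the bounds F-test for a level
    (cointegrating) relationship, long- and short-run elasticity estimation,
    stochastic counterfactual shock simulation from multivariate-normal
    parameter draws, recursive-residual CUSUM/CUSUMSQ stability tests, a suite
    of residual diagnostics, and a seeded synthetic data generator with known
    ground truth for validating every stage of the workflow.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    lmtest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
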