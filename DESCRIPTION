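Package: alpacatestis
Title: Testicular Growth Modelling and Sperm-Presence Thresholds for Alpacas
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to analyse the onset of sperm production in male alpacas
    (Vicugna pacos) from cross-sectional testicular measurements. Fits a
    Bayesian logistic-in-age growth model for mean testicular length (null,
    increment, and increment-with-body-condition variants) by adaptive
    random-walk Metropolis MCMC and compares variants by the deviance
    information criterion (DIC); fits binomial-logit models of sperm presence
    on age or testicular length with Wald tests, AIC and pseudo-R2 measures;
    inverts the fitted sperm-presence curve into management thresholds (the
    length above which sperm production is near-certain and below which it is
    near-impossible); bins cohorts into age-by-length contingency tables; and
    generates seeded synthetic cohorts plus deterministic table fixtures for
    testing the whole analysis without access to raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
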