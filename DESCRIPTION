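Package: svyreri
Title: Survey-Weighted Risk-Ratio Models with Additive Interaction on the
    Excess-Case Scale
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits modified Poisson (log-link Poisson working likelihood)
    risk-ratio models to binary health outcomes under a stratified,
    clustered, weighted survey design, with design-based linearized
    sandwich variance.  Supports multiple imputation of missing exposure
    components, covariates and outcomes via chained equations, Rubin's
    rules pooling, and conversion of relative-scale race-by-exposure
    interaction into additive-scale summaries: the relative excess risk
    due to interaction (RERI), the interaction contrast, and excess cases
    per 1000 with Monte-Carlo resampling confidence intervals.  Includes a
    synthetic cohort generator emulating a multi-wave adolescent health
    survey (stratified cluster sampling, adverse childhood experience
    components, biomarkers, seven binary outcomes under a log-linear risk
    model) so the full pipeline is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    knitr
Config/testthat/edition: 3
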