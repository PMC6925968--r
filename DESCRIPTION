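Package: svysim
Title: Simulation-Based Evaluation of Weighting and Variance Estimation
    for Complex Health Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Generates synthetic multi-stage health-facility and household
    survey microdata with exact inverse-probability design weights, emulating
    the structure of Service Provision Assessment (facility, provider, client)
    and Demographic and Health Survey (enumeration area, household, woman)
    designs with certainty strata, probability-proportional-to-size selection
    and observation caps.  Provides weighted (Hajek) and unweighted point
    estimation, three standard-error methods (stratified cluster bootstrap,
    single-stage design-based linearization, and multi-stage linearization
    with finite population corrections), and a stratified-resampling
    simulation harness that evaluates estimators by bias, variance, mean
    squared error, coverage probability and confidence-interval length.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
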