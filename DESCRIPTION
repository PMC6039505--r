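Package: metaprev
Title: Multi-Study Disease Prevalence Estimation by Standardization and
    Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating disease prevalence from stratified case
    counts collected across several studies. Implements direct age and sex
    standardization to a reference population with gamma-method confidence
    intervals, per-stratum random-effects meta-analysis of log prevalence
    with I-squared heterogeneity statistics, a composite age-standardized
    meta-estimate with Monte-Carlo percentile confidence intervals,
    person-time prevalence for longitudinal cohorts with bootstrap
    confidence intervals, projection of case burden onto population
    forecasts, and simulators that generate multi-study count tables and
    aging cohorts for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    metafor,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
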