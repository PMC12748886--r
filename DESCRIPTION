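Package: heatattr
Title: Attributing Trends in Heat-Related Excess Mortality to Climate
    Change and Changing Vulnerability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage time-series framework for attributing temporal trends
    in warm-season heat-related excess mortality to anthropogenic climate
    change while disentangling the role of changing population vulnerability.
    Builds observation-based counterfactual temperature series by removing
    the global-warming signal (singular spectrum analysis smoothing of
    global mean surface temperature anomalies, city-specific scaling
    regressions, and a 9-member uncertainty ensemble); fits city-by-subperiod
    quasi-Poisson distributed-lag non-linear mortality models and reduces
    them to cumulative exposure-response coefficients; pools coefficients
    with a longitudinal multivariate mixed-effects meta-regression (maximum
    likelihood) including meta-predictor selection, heterogeneity statistics
    and factual/counterfactual best linear unbiased predictions; and computes
    minimum-mortality temperatures, attributable deaths and fractions under
    factual and counterfactual scenarios with Monte Carlo empirical
    confidence intervals and trend tests. Includes a fully specified
    synthetic multi-city world with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    splines,
    stats,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
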