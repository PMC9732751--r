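Package: telecost
Title: Societal-Perspective Cost and Avoided-Travel Emissions Analysis for
    Telemedicine Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cost-minimization analysis of two-arm telemedicine versus
    in-clinic trials from the societal perspective: per-patient travel
    costs, time costs and production losses; arm-level cost summaries
    split by employment status; avoided-travel emissions for five
    pollutants with passenger-kilometer emission factors; environmental
    cost valuation under alternative carbon-price regimes; annual
    extrapolation scenarios; deterministic sensitivity analysis; and the
    supporting nonparametric trial statistics (Mann-Whitney U, Fisher
    exact, a priori sample size via the noncentral t distribution).
    Includes a synthetic two-arm cohort generator and a packaged
    reference summary of the motivating German follow-up-care trial so
    every stage runs without access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
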