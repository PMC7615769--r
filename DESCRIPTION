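Package: dbmtrend
Title: Bayesian Hierarchical Meta-Regression for Underweight and Obesity Trends
Version: 0.1.0
Authors@R: person("NCD Modelling", "Contributors", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates national trends in the prevalence of underweight
    (or thinness) and obesity from heterogeneous population-based studies
    using a Bayesian hierarchical meta-regression with second-order
    random-walk time trends, hierarchical age splines, and adjustment for
    subnational and community survey coverage.  All reported quantities
    (double burden of malnutrition, obesity share, age-standardised
    prevalence, posterior probabilities of change and dominance, persons
    affected) are computed at the posterior draw level.  Includes a
    synthetic study-database generator so the whole pipeline is testable
    without access to governed survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
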