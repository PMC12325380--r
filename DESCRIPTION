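Package: twinwell
Title: Twin Models of Child Wellbeing Across Environmental Disruption
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and maximum-likelihood estimation tools for genetically
    informative studies of parent-rated child wellbeing measured on the 0-10
    Cantril ladder. Provides a seeded synthetic twin-cohort generator with
    known additive-genetic (A), shared-environment (C) and non-shared
    environment (E) structure; raw-data (full-information) multivariate-normal
    likelihoods for arbitrary missing-data patterns; a four-period correlated
    factors ACE model with genetic and environmental correlations and
    standardized (co)variance shares; a psychometric multi-rater twin model
    separating rater agreement from rater-specific variance including rater
    bias; random-intercept linear mixed models of mean wellbeing trends with
    estimated marginal means; and a pipeline driver that writes tabular
    reports from a single seeded configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nlme,
    optparse
Config/testthat/edition: 3
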