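Package: plantcoex
Title: Pairwise Coexistence Analysis for Competing Annual Plants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Beverton-Holt annual-plant competition models to
    density-gradient seed-production data by negative-binomial maximum
    likelihood, decomposes the competitive outcome into niche overlap and
    average fitness differences following modern coexistence theory,
    computes mutual-invasibility (low-density invasion) growth rates, and
    classifies the long-term outcome per environment. Includes stratified
    bootstrap and first/second-order Taylor error propagation with a
    Monte-Carlo cross-check, simplified negative-binomial GLM analyses of
    field survey data, synthetic-data generators that emulate a
    density-gradient pot experiment, and a configurable end-to-end
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
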