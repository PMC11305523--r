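Package: obesim
Title: Microevolutionary Simulation and Cross-Country Analysis of Obesity
Version: 0.1.0
Authors@R:
    person("obesim", "maintainers", email = "obesim@example.org", role = c("aut", "cre"))
Description: Forward-time simulation of a highly polygenic body-mass-index
    trait under relaxation of childbirth-mortality selection, together with
    an ecological cross-country statistics pipeline (log transforms,
    correlation matrices, partial correlations, multivariate and stepwise
    regression, median-split subgroup analysis, exponential curve fits, and
    a maternal-mortality by obesity contingency analysis) and seeded
    synthetic-data generators so every stage is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
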