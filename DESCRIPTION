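Package: mhrte
Title: Stochastic Fuzzy DEA Assessment of Mental-Health Service Efficiency
Version: 0.1.0
Authors@R:
    person("Analytics", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Decision-support pipeline for assessing the relative technical
    efficiency (RTE) of mental-health services classified with DESDE-LTC
    codes. Implements pattern-of-use linear regression, Monte Carlo
    perturbation of service rates with triangular distributions, a
    knowledge-based fuzzy transformation of rates onto a DEA-favourable
    scale, input-oriented variable-returns-to-scale data envelopment
    analysis with two-phase slack maximisation and weak-efficiency
    classification, RTE probability statistics, and quartile-based
    workforce comparisons with the Mann-Whitney U test. Includes a seeded
    synthetic-data generator that reproduces the statistical structure of
    a regional service ecosystem so the whole pipeline is testable without
    confidential data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
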