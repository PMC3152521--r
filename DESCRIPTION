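Package: insomod
Title: Decision-Tree Cost-Utility Modelling of Insomnia Treatment Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A decision-analytic economic evaluation toolkit for insomnia
    treatment pathways, built around the New Zealand care-seeking model:
    a decision-tree cost engine with pathway enumeration and expected-cost
    rollback, event-level micro-costing from unit resource costs and
    utilisation volumes, mixture algebra splitting per-capita health
    expenditure into insomniac and non-insomniac means, cost-utility
    metrics (QALY gains, net benefit, cost per QALY) with prevalence-based
    population scaling, and multivariate probabilistic sensitivity analysis
    by Monte Carlo sampling from triangular distributions. The packaged
    model ships as plain-text configuration (unit costs, utilisation
    matrix, population parameters, tree topology) together with a synthetic
    generator for the branch probabilities the source tables do not print.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
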