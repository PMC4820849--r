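Package: conflictplan
Title: Conflict-Risk-Aware Protected-Area Planning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for systematic conservation planning under armed-conflict
    risk. Estimates per-planning-unit conflict risk from geo-referenced event
    histories via impact zones and a logistic model, transforms minimum-set
    reserve-selection problems under four attitudes to risk (ignorant,
    avoiding, accounting, sensitive) including binomial and Poisson-binomial
    reliability targets, solves them with greedy and simulated-annealing
    heuristics (plus an exact brute-force oracle for small instances), and
    evaluates candidate networks by Monte Carlo simulation of conflict losses
    (targets met, cost, return on investment). Includes a synthetic landscape
    and conflict-history generator so the full pipeline can be exercised
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
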