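Package: restlessbandit
Title: Restless Four-Armed Bandit Simulation, Kalman-Softmax Modelling, and
    Decision-Efficiency Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the restless four-armed bandit task (arm payoffs drift
    in a decaying Gaussian random walk), models choice behavior with a
    Kalman-filter learner and softmax decision rule, fits the model by
    maximum likelihood with shared learning parameters and per-subject
    inverse temperatures, labels trials as explorative or exploitative from
    the fitted beliefs, computes speed-accuracy decision efficiency (payoff
    divided by response time) with 2x2 mixed-design ANOVAs, and runs
    second-level statistics on region-of-interest activity tables
    (condition contrasts, choice-by-group ANOVA, multiple regression of
    efficiency on ROI activity). Includes a seeded synthetic-cohort
    generator so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
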