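Package: oblearn
Title: Observational Reinforcement Learning and Partner Selection Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation, model fitting and analysis tools for observational
    reinforcement learning experiments in which participants watch noisy
    Q-learning partners play a three-armed bandit, select whom to learn
    from, and then learn by observation.  Provides simulated bandit
    partners, observational-learning models that mix imitation of actions
    with vicarious reward learning, hierarchical Bayesian fitting with
    WAIC model comparison, model and parameter recovery studies,
    block-level partner metrics (performance, predictability, information
    gain), mixed-effects regression analyses of partner selection and
    learning style, and posterior predictive checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    lme4,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    tidyr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
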