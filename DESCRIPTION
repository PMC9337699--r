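Package: jarinfer
Title: Bayesian and Heuristic Observer Analysis for the Jar-Discrimination Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis of a two-alternative jar-discrimination
    task with asymmetric evidence. Provides the task environment and ideal
    observer (log-likelihood-ratio beliefs, rare-ball thresholds, exact
    response probabilities), six stochastic observer models (three Bayesian,
    three heuristic), a synthetic-cohort generator emulating the full study
    design with exclusion rules, grid-based Bayesian parameter estimation
    with informative priors, Bayes-factor model selection with
    cross-validation and model-recovery studies, psychometric decomposition
    of choice errors into bias, noise and variance, and strategy-complexity
    analysis via mutual information, a rate-distortion accuracy bound and
    algorithmic operation counts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), pracma, jsonlite, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
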