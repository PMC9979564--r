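Package: sepsisrl
Title: Reinforcement-Learning Treatment Policies for Sepsis with Robust
    Off-Policy Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for learning and evaluating intensive-care sepsis treatment
    policies from retrospective trajectories. Implements a clinically guided
    family of reward functions over severity-indicator changes with weights
    learned by inverse reinforcement learning on top of a dueling double
    deep Q-network, tree-ensemble discovery of the features most critical to
    mortality, a suite of off-policy evaluation estimators (importance
    sampling, weighted importance sampling, doubly robust, weighted doubly
    robust, and the dueling-weight DW and DWDR estimators), and a calibration
    procedure mapping expected returns to mortality. Ships an exact tabular-MDP
    oracle and a synthetic ICU cohort simulator so every stage is testable
    without access to credentialed clinical databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    purrr,
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
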