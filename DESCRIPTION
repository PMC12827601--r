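Package: trustsim
Title: Agent-Based Simulation of Trust-Mediated Human-AI Decision Making
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An agent-based Monte Carlo framework for studying human-AI
    complementarity in binary and multi-option decision tasks. Synthetic
    decision-makers are characterised by competence (probability the primary
    decision is correct), certainty (probability the primary decision is kept
    rather than reversed out of self-doubt) and baseline trust in an AI
    adviser. AI advisers vary in competence and, in the conditional-trust
    mode, report a confidence score that modulates the human's effective
    trust through a sigmoid link. The package provides the per-trial decision
    engine, closed-form and quadrature oracles for every simulated
    expectation, factorial scenario runners with deterministic substream
    seeding, tidy summaries of relative improvement across the agent grid,
    plotting helpers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
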