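Package: banditlearn
Title: Reinforcement-Learning and Recurrent-Network Models of Two-Armed
    Bandit Choice Behaviour
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits and interrogates trial-by-trial models of human choice in a
    block-structured two-armed bandit task. Implements Q-learning (QL),
    Q-learning with perseveration (QLP), a generalised Q-learning model (GQL)
    that tracks multiple reward values and action histories per action, a
    lagged logistic-regression model (LIN), and a long short-term memory
    (LSTM) network trained by maximum likelihood to imitate choice sequences.
    Provides exact analytic gradients for all likelihoods, Adam and L-BFGS
    optimisation with iteration checkpointing for early stopping,
    leave-one-out cross-validation and hyperparameter selection, on-policy,
    off-policy and mixed simulation probes, behavioural summary statistics
    (stay probabilities, run-length structure), diagnostic-label
    classification, and a synthetic-cohort generator with healthy-like,
    depression-like and bipolar-like choice phenotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
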