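Package: opponentSR
Title: Opponent Dual-System Reinforcement Learning with Successor and
    Individual Representations
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Simulates a reinforcement-learning agent composed of two
    parallel learning systems, each using either the successor
    representation (SR) or the individual (punctate) representation (IR)
    of states, with separate learning rates for positive and negative
    temporal-difference reward prediction errors. Provides the dynamic
    reward-navigation grid-world task and its variants, two-stage
    decision tasks with drifting or switching reward probabilities, and
    the experiment machinery (parameter sweeps over learning-rate
    ratios, repeated-sweep best-condition frequencies, learning curves
    with placement-epoch attribution, and state-value snapshots) used to
    characterise when an appetitive SR-based system paired with an
    aversive IR-based system outperforms other combinations.
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
    yaml,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
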