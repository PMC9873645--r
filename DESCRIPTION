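Package: ipdlearn
Title: Learning Dynamics of Cooperation in the Iterated Prisoner's Dilemma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to dissect temporal-difference reinforcement learning of
    memory-one strategies in the iterated Prisoner's Dilemma. Implements
    epsilon-greedy Expected SARSA self-play (fully online and a sample-batch
    variant), the deterministic strategy-average learning dynamics in
    state-action-value space, and mutual best-response networks over the 256
    joint pure strategies, including analytic stability conditions for the
    All-Defect, Grim-Trigger and Win-Stay-Lose-Shift equilibria, basins of
    attraction, and reproducible simulation drivers with Wilson-score
    confidence intervals.
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
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
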