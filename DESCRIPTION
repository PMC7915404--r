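Package: seirja
Title: Coupled Simulation of Public-Opinion Dissemination and Polarization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Agent-based simulation of how public opinion spreads and
    polarizes on online social networks. An epidemic-style
    uninformed/silent/communication/immune (SEIR) state machine, driven by
    each agent's communicating willingness and a forgetting clock, is
    coupled to a heterogeneous bounded-confidence opinion dynamic of the
    Jager-Amblard family in which tie embeddedness, conservatism and
    conformity modulate every pairwise opinion exchange. Includes
    scale-free, small-world and random network substrates, classic SEIR and
    classic Jager-Amblard baselines, polarizability and comment-curve
    metrics, Monte-Carlo ensemble utilities, scripted parameter sweeps, and
    a synthetic comment-stream generator for empirical-style scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
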