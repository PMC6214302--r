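Package: rbncontrol
Title: Evolving Compact Control Rules for Random Boolean Networks with
    the XCS Learning Classifier System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for steering NK random Boolean networks -- minimal
    models of gene-regulatory dynamics -- from any state into a chosen
    target attractor. Networks are generated, simulated synchronously
    and analysed exhaustively (attractors, basins of attraction,
    state-space graphs). Control policies are sets of ternary
    condition-action rules (conditions over {0,1,#}, actions that flip a
    single node or do nothing) evolved by an accuracy-based learning
    classifier system (XCS) combining reinforcement learning with
    genetic-algorithm rule discovery, followed by a numerosity-ordered
    rule-compression step that extracts the smallest fully-covering rule
    set with minimal average interventions. The trial loop and
    classifier engine are implemented in C++ for speed.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
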