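Package: metatutor
Title: Optimal Planning-Strategy Discovery and Metacognitive Feedback for
    Mouselab-MDP Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying and teaching far-sighted planning in
    Mouselab-MDP process-tracing tasks. Defines click-cost planning
    environments over reward trees, solves the corresponding metalevel
    Markov decision process exactly by backward induction over belief
    states (with a compiled canonical-state core), converts the regret of
    each planning operation into calibrated delay penalties and
    instructional messages (an intelligent metacognitive tutor), normalizes
    trial scores against chance and optimal anchors, and simulates
    complete scripted-participant sessions so the whole pipeline can be
    exercised without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
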