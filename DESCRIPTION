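Package: gestnet
Title: Partial-Correlation Network Analysis of Schizotypy and Gesture
    Processing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scores the Schizotypal Personality Questionnaire-Brief
    (SPQ-B), the Brief Assessment of Gesture (BAG) scale, and a
    speech-gesture matching task into nine subscale variables, and
    analyses their joint structure as a psychometric network: bivariate
    Spearman correlations, a non-regularized partial Spearman correlation
    network with nonparametric bootstrap percentile-interval edge
    selection, fast greedy (Clauset-Newman-Moore) community detection
    with a deterministic tie-break contract, bridge centralities
    (expected influence, closeness, betweenness) with bootstrapped
    difference tests, node predictability, and average and modal network
    controllability under discrete-time linear dynamics. A synthetic-data
    generator with a known ground-truth partial-correlation network makes
    every stage testable end-to-end without access to participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
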