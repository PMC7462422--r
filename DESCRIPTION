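Package: idiffr
Title: Differential Identifiability of Functional Connectomes and Their Network Properties
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying subject fingerprints in test-retest functional
    connectomes. Generates synthetic cohorts of valid correlation-matrix
    connectomes with tunable subject, condition and noise components; computes
    eight weighted-graph network properties (degree strength, shortest path
    length, search information, mean first passage time, driftness,
    communicability, clustering coefficient, betweenness centrality); applies
    a group-level PCA decomposition-reconstruction framework to maximise
    differential identifiability (I_diff) over the number of retained
    components, in both orders (reconstruct connectomes then derive
    properties, or reconstruct the properties themselves); and quantifies
    task sensitivity of each property with one-way intraclass correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
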