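Package: hormonet
Title: Phytohormone Crosstalk Network Analysis from Pathway Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds enzyme correlation networks from BioCyc-style pathway
    flat-files using the shared-substrate rule, restricts them to hormone
    crosstalk subnetworks from hormone-to-pathway annotations, ranks hub
    enzymes with twelve centrality indices (including maximal clique
    centrality, density of maximum neighborhood component, edge percolated
    component and bottleneck), detects overlapping communities by greedy
    cohesiveness growth, extracts consecutive metabolic routes as maximum
    simple paths in a producer/consumer coupling graph, enumerates circular
    control units of transcription factors in co-target networks, and
    overlays transcriptome and proteome evidence on routes. Ships a synthetic
    data generator with planted structures and a packaged curated fixture of
    an Arabidopsis phytohormone crosstalk network.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    igraph,
    readr,
    rlang,
    tibble,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
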