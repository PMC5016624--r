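Package: multiohc
Title: Multirelational Social Network Analysis of Online Health Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Builds directed communication subnetworks (blogs, message
    boards, group discussions, private messages) from timestamped
    post/read event logs of an online health community, under an
    information-flow tie rule where an edge A -> B means content
    contributed by A was read by B. Characterizes each layer's topology
    (density, dyadic reciprocity, strongly connected components, shortest
    paths, degree distributions), quantifies cross-layer structural
    similarity (multiplexity counts, degree-rank correlations,
    edge-overlap Jaccard coefficients), analyzes the temporal order in
    which ties form across layers, and profiles users by cross-layer
    centrality with Gaussian mixture models to relate network position to
    smoking-abstinence outcomes. A seeded synthetic community generator
    makes the full pipeline reproducible end to end without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
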