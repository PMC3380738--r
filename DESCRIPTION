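Package: overclust
Title: Overlap Analysis and Refinement of Protein Complex Predictions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting protein complexes from protein-protein
    interaction networks by analysing and refining overlapping graph
    clusters. Implements entropy-based seed-growth clustering (single-seed
    and triangle-seeded variants), per-cluster overlap statistics (overlap
    rate, overlap coverage, overlapping consistency), a consensus-threshold
    overlap refinement algorithm that merges strongly overlapping clusters,
    and f-measure evaluation against gold-standard complex catalogs.
    Includes readers for plain edge lists, MCL-style cluster files and
    complex catalogs, a planted-complex synthetic benchmark generator, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
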