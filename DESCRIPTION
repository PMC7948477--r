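Package: proxikit
Title: Differential Proteomics, Pathway Crosstalk, and Interactome Proximity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A seeded, testable pipeline from multi-condition protein
    abundance tables to network-level biological claims. Implements
    peptide/protein normalization and aggregation for label-free and
    targeted (PRM-style) proteomics, multi-group differential abundance
    with Benjamini-Hochberg q-values and fold-change enrichment calls,
    hypergeometric pathway over-representation, a Jaccard-weighted
    pathway crosstalk graph with modularity modules, and an interactome
    closest-distance proximity statistic with a degree-preserving
    randomization null and empirical p-values. A synthetic-data module
    generates networks, pathway collections, and abundance tables with
    known ground truth so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
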