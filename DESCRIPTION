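Package: complexpert
Title: Knowledge-Driven Protein Complex Extraction from PPI Networks
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A knowledge-driven toolkit for extracting protein complexes from
    protein-protein interaction (PPI) networks. A forward-chaining rule engine
    analyses an input network (size, curated-core fraction, scale-free test),
    suggests and justifies preprocessing and clustering strategies, and runs
    the corresponding algorithms: false-negative interaction prediction by
    defective-clique completion, false-positive filtering by edge betweenness
    and combined topological scores, and complex extraction with Markov
    clustering (MCL), MCODE and restricted neighbourhood search clustering
    (RNSC). Purification steps are audited for core-interaction preservation,
    clusters are scored by hypergeometric term enrichment against a local
    annotation map, and every run records a three-layer, backtrackable
    workflow trace with checkpoints. Ships a 34-protein yeast DIP subnetwork
    fixture and synthetic-network generators so all functionality is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
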