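Package: coherentpartition
Title: Protein Complex Prediction by Partitioning PPI Networks into
    Biclique-Spanned Subgraphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein complexes from protein-protein interaction
    (PPI) networks by partitioning the network into biclique-spanned
    subgraphs (graphs whose complement is disconnected), a class that
    covers the full density continuum of real complexes from stars
    through complete bipartite graphs to cliques.  Implements the
    parameter-free greedy coherent-partition algorithm based on
    second-neighborhood candidate clusters scored by a cut-ratio
    criterion, a full suite of cluster-versus-gold-standard evaluation
    measures (sensitivity, positive predictive value, accuracy,
    separation, fraction match, maximum matching ratio, Jaccard and
    neighborhood-affinity precision/recall/F-measures, modularity and a
    composite score), a seeded generator of networks with planted
    complexes for validation, and readers/writers for edge-list and
    flat complex-catalogue files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
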