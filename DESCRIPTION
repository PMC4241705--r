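Package: pinalign
Title: Local Alignment of Protein-Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pairwise local alignment of weighted protein-protein
    interaction networks. Partitions the first network into hub-centred
    clusters, grows candidate subnetwork alignments by a beam-pruned
    dynamic-programming merge guided by hierarchical agglomeration over a
    connectivity distance, scores candidates by sequence similarity
    (node score) and conserved-edge structure (structural score), and
    extracts the final alignment from a candidate-derived similarity
    bipartite graph using weighted bipartite matching with a
    duplication-aware one-to-two ("DMatch") stage. Includes
    ortholog-group based specificity and sensitivity metrics and a
    synthetic network-pair generator with planted orthology for
    validation.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
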