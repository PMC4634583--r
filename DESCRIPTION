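Package: ppimirfs
Title: Plant miRNA Functional Similarity from GO-Weighted Protein
    Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scores the functional similarity of plant miRNA pairs from
    the connectivity of their target genes in a protein-protein
    interaction network whose edges are weighted by the graph-based
    (Wang) Gene Ontology semantic similarity of the interacting genes.
    Gene pairs are scored by the best accumulated edge-weight product
    over minimum-hop shortest paths (a weighted breadth-first search
    with dominance pruning), and miRNA pairs by a modified best-match
    average over their target gene sets that excludes genes absent from
    the network.  Includes readers for OBO ontologies, GAF annotations
    and tabular edge lists, a synthetic-fixture generator, and an
    evaluation suite (family/cluster/stress pair partitions, rank-based
    group comparisons, and 1-vs-99 prioritization ROC/AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
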