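Package: multiwalk
Title: Random Walk with Restart on Multigraph and Heterogeneous
    Gene-Phenotype Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Network propagation for candidate disease-gene
    prioritization. Merges several weighted gene networks into a
    multigraph whose transition probabilities are the expectation over
    the layers a node belongs to, and runs a random walk with restart
    on the merged network (RWRM). A complex heterogeneous network (CHN)
    extension couples the gene multigraph to a phenotype similarity
    network through a bipartite gene-phenotype association matrix, with
    a jumping probability that lets the walker cross between the two
    subnetworks at bridging nodes. Includes K-nearest-neighbour
    similarity-graph construction, annotation-overlap gene functional
    similarity, a leave-one-out cross-validation protocol with
    artificial linkage intervals and rank-based ROC/AUC, a seeded
    synthetic benchmark generator, TSV readers and writers, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
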