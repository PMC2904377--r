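Package: netdendro
Title: Iterative Hierarchical Clustering of Undirected Networks
Version: 1.0.0
Authors@R: person("netdendro", "maintainers", email = "netdendro@example.org",
    role = c("aut", "cre"))
Description: Converts undirected interaction networks (e.g. protein-protein
    interaction graphs) into dendrograms by iterative hierarchical
    clustering.  Three randomized partitioning algorithms (greedy clique
    growth, random clique merging, and star collapse) are applied over many
    iterations to accumulate a secondary-distance matrix: the fraction of
    iterations in which each pair of nodes was clustered apart.  Dendrograms
    are built from that matrix with UPGMA or midpoint-rooted neighbor
    joining, and the statistically optimal partition of each tree is
    extracted with two criteria: Newman-Girvan modularity (Q) and a
    cumulative-hypergeometric surprise index (H).  Includes a planted
    caveman-graph benchmark generator with controlled degradation, writers
    for Newick, MEGA 4 distance, Cytoscape 2.x attribute and plain-text
    partition files, and a command-line front end.
License: GPL-3
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    phangorn,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
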