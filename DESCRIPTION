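Package: tmnet
Title: Association Rule Mining and Network Pharmacology for Multicomponent
    Traditional-Medicine Prescriptions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for mining disease-material association rules from
    multicomponent traditional-medicine prescription records (level-wise
    apriori with support, confidence and lift), building the disease-material
    bipartite network and radar summary tables, assembling multi-source
    protein-protein interaction networks with degree and eigenvector
    centrality and top-percentile hub extraction, prioritizing disease nodes
    by random walk with restart over a heterogeneous compound-target-disease
    network, and hypergeometric over-representation analysis against GMT
    gene-set libraries with Benjamini-Hochberg adjustment. Includes synthetic
    generators for every input (prescription databases with planted rules,
    scale-free PPI graphs, heterogeneous networks, gene-set libraries) so the
    full pipeline runs reproducibly without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
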