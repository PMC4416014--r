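Package: mixmod
Title: Mixed-Modularity Module Detection in Two-Class Heterogeneous Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects mixed modules (communities containing both node classes)
    in two-class heterogeneous networks (2-HNs) such as chemical-gene and
    drug-target systems. Implements the mixed-modularity quality function --
    the mean of Newman-Girvan modularity on the two within-class channels and
    Barber bipartite modularity on the cross-class channel -- together with a
    Louvain-style two-phase optimizer, a labeled benchmark generator with
    planted mixed modules (LFR-style subnetworks coupled by a tunable
    bipartite channel), partition-comparison metrics (normalized mutual
    information and classification accuracy), and helpers for building
    application networks from chemical fingerprints and interaction tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
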