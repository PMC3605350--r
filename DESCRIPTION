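Package: AffineDO
Title: Direct Optimization and Affine-DO Heuristics for the Tree Alignment Problem
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Heuristics for the Tree Alignment Problem (TAP): given unaligned DNA
    sequences at the leaves of a binary phylogenetic tree and an edit cost model,
    assign sequences to the internal vertices so that the summed edge-wise alignment
    cost is minimized. Implements Direct Optimization (DO) over Reduced Alignment
    Graphs (sequences over the powerset alphabet), its affine-gap extension Affine-DO
    with the four-matrix Gotoh-style recurrences and the indel-aware median, the
    Fixed States 2-approximation, approximate and exact iterative improvement, an
    exact three-sequence dynamic-programming oracle for small instances, and a
    sequence-evolution simulator (substitutions plus power-law indels on random
    trees) for benchmarking. Pairwise kernels are implemented in C++.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    ape,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Alignment, Phylogenetics, Software
RoxygenNote: 7.3.3
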