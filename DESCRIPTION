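Package: RNASwitchDesign
Title: Multi-Objective Design of Interacting RNA Pairs (RNA-RNA Switches)
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computational design of molecular switches composed of two
    interacting RNA strands. Given extended target secondary structures for
    the two isolated strands and for their hybridized complex, a
    constraint-dominance NSGA-II genetic algorithm evolves Pareto-optimal
    sequence pairs that minimize structure distance, an interaction-seed /
    hybridization energy term, and the free energy of the complex, subject
    to GC-content constraints and IUPAC sequence constraints. Targets may be
    written in extended dot-bracket notation (with wildcards and a strand
    separator) or in the compact S+ shape notation with sequence/structure
    motifs. A deterministic built-in structure predictor supporting
    intermolecular duplex regions (and hence kissing-hairpin topologies) is
    provided, together with an adapter contract for external thermodynamic
    predictors, a designable-target fixture generator and a benchmark
    harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    igraph,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
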