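Package: muklock
Title: MatS Discovery, Cross-Link Topology and Equilibrium Binding Analysis
    for MukBEF Chromosome Entrapment Experiments
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for studying how the bacterial SMC complex
    MukBEF entraps chromosomal DNA. Discovers candidate matS sites on
    (circular) genomes by degenerate and edit-distance palindrome scanning
    ranked against the replication terminus predicted from cumulative GC
    skew; quantifies gel lanes with moving-median background subtraction and
    Bayesian credible intervals; models multi-site cysteine cross-linking
    species combinatorially and detects covalent protein circles; infers DNA
    threading topologies from catenation parity in chromosome entrapment
    assays; fits equilibrium dissociation constants to EMSA titrations with
    a depletion-aware rate-equation model; and measures DNA crossing angles
    and minimum backbone van der Waals distances on atomic structures.
    Seeded generators emulate every input class so the whole pipeline is
    testable without external data.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    bio3d,
    deSolve,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
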