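Package: ancientMito
Title: Ancient Mitochondrial Genome Reconstruction, Authentication and
    Phylogenetic Placement
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for working with ancient-DNA shotgun/capture data aimed at
    mitochondrial genomes: simulation of short, deaminated ancient reads from
    circular references (Briggs-type single-stranded overhang damage model),
    paired-end read merging with adapter read-through removal, iterative
    reference-guided assembly with damage-aware mapping and duplicate removal,
    terminal C-to-T / G-to-A misincorporation profiling with an authenticity
    verdict, phylogenetic placement (GTR+G+I pruning likelihood, Fitch
    parsimony, NNI search, bootstrap supports, outgroup rooting, cytochrome-b
    mismatch counting), and collagen stable-isotope quality control with
    convex-hull niche-overlap analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    ape,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    Matrix,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
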