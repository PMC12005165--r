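Package: allokit
Title: Haplotype-Resolved Allotetraploid Assembly Curation Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for scaffolding and curating haplotype-resolved
    assemblies of allotetraploid genomes. Detects allelic unitigs through
    shared single-copy protein markers, prunes Hi-C read pairs that link
    allelic unitigs before scaffolding, assigns chromosomes to progenitor
    subgenomes from windowed read-depth of candidate-progenitor
    alignments, detects coverage-switch rearrangements (homoeologous
    exchanges and translocations), clusters chromosomes by k-mer
    composition and frequency signatures with a strict subgenome-cluster
    validity check, and generates telomere-motif and N-gap curation
    tracks. Ships a synthetic allotetraploid simulator so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
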