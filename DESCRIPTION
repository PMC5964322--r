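Package: crosslinkr
Title: Simulation and Analysis of iCLIP Crosslink Data with 3'UTR Motif
    Statistics and Sholl Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for characterizing the mRNA interactome of an RNA-binding
    protein from iCLIP sequencing data. Provides a ground-truth synthetic-data
    generator (transcript models, sequences with planted uridine-rich motifs
    and miRNA seed sites, multiplexed reads with random barcodes and PCR
    duplication), crosslink-event calling under the cDNA truncation model with
    UMI-based duplicate collapse, per-transcript permutation-FDR peak calling
    and target derivation, transcript-feature attribution, 3'UTR k-mer and
    miRNA 7mer-A1 seed-match statistics with bound/unbound comparisons,
    hypergeometric set-overlap enrichment, crosslink-centered positional
    nucleotide profiles, a seed-proximity permutation test, and Sholl
    intersection profiling of neuron reconstructions with group comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
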