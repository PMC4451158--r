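Package: its2barcode
Title: ITS2 DNA Barcoding for Medicinal Plant Species Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for DNA-barcode species identification with the nuclear
    ribosomal ITS2 region. Reads labelled barcode FASTA files, trims amplicons
    at universal primers and annotates the partial 5.8S / ITS2 / partial 28S
    sub-regions, aligns sequences (affine-gap pairwise and progressive
    multiple alignment), computes Kimura 2-parameter distances with per-species
    intra/interspecific summaries, classifies alignment columns and detects
    species-diagnostic sites, assigns species by nearest genetic distance and
    by local-alignment top hit (BLAST1-style) with leave-one-out evaluation,
    and builds neighbor-joining trees with column-bootstrap supports and
    monophyly tests. A seeded simulator generates species-structured haplotype
    datasets with full ground truth so every stage of the pipeline is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
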