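Package: lcnbait
Title: Clade-Specific Target-Capture Bait Panel Design and Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for designing and evaluating clade-specific RNA-bait
    panels for target-capture sequencing of low-copy nuclear (LCN) genes.
    Detects putative single- to low-copy ortholog groups across congeneric
    transcriptome sets by reciprocal best k-mer match, transfers intron-exon
    boundaries from an annotated reference by alignment, filters loci on
    species presence, internal exon length and SNP density, tiles 80-base
    baits across exons with configurable tiling depth, and screens baits for
    low complexity, blacklist (high-copy/plastid) matches, GC content,
    melting temperature and redundancy. Evaluates capture experiments with
    on-target read fractions, per-locus coverage, recovery matrices and
    paralog flags, and compares bait panels by sequence overlap and target
    surplus. Includes a seeded simulator (Jukes-Cantor evolution on a tree)
    that generates transcript sets, capture reads and a ground-truth manifest
    so the whole pipeline can be exercised end-to-end on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
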