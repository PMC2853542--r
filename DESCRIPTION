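Package: epicmine
Title: Discovery of Exon-Primed Intron-Crossing (EPIC) Markers from
    Whole-Genome Comparisons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A comparative-genomics pipeline for mining exon-primed
    intron-crossing (EPIC) markers: short introns flanked by single-copy,
    conserved coding exons, suitable for designing universal primers that
    amplify across a broad taxonomic range. Given one annotated query
    genome and one or more reference genomes, the pipeline extracts large
    coding segments, removes multi-copy sequences by all-vs-all local
    alignment, maps flanking exons onto each reference with an affine-gap
    Smith-Waterman engine using a mild mismatch penalty, screens introns
    by size and flanking-exon identity, merges nearby qualifying introns,
    and writes a marker catalogue (TSV/FASTA/BED). Companion tools compute
    amplification-success statistics for marker panels (per-locus success
    rates, pairwise amplifiability similarity, p-distances, and their
    correlations) and simulate multi-species genome sets with known gene
    structure, divergence and planted duplications for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape
Config/testthat/edition: 3
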