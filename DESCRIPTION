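Package: trioase
Title: Trio-Binning Read Classification and Allele-Specific Expression
    Analysis for Hybrid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing interspecific hybrid genomes and
    transcriptomes from a parent-parent-hybrid trio. Implements k-mer
    based trio binning of sequencing reads (solid k-mers, haplotype
    diagnostic hap-mers, maternal/paternal/ambiguous read classification)
    with phasing quality control (hap-mer recovery, contamination, k-mer
    completeness, Phred-scaled assembly QV) and telomere motif scanning;
    diagnostic-SNP and haplotype-resolved allele-specific expression
    (allelic read assignment, allele-pair definition via collinear gene
    blocks and orthogroups, allelic count matrices); and heterosis
    expression-mode classification against the mid-parent value
    (additive, dominant, overdominant) with a negative-binomial
    two-group test, ASE ratio thresholding, and pathway-level
    reporting. A synthetic-data module generates fully labelled
    parent/hybrid fixtures so every stage can be validated against
    planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    rtracklayer,
    Rcpp,
    stats,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    DESeq2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
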