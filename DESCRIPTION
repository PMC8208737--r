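Package: haplopath
Title: Metagenomic Haplotype Recovery from Pairwise SNV Co-Occurrence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Recovers gene-scale haplotypes from a metagenomic sample in
    which an unknown number of community members carry variants of the same
    genomic region. Aligned reads are summarised into a pairwise single
    nucleotide variant (SNV) co-occurrence matrix that aggregates, for every
    ordered pair of variant sites, the symbols observed together on single
    reads. The matrix induces a probabilistically weighted graph over
    per-site symbols; a greedy traversal conditioned on a configurable
    lookback window walks the graph to emit candidate haplotypes, evidence
    for each recovered path is multiplicatively depleted so subsequent
    traversals find alternative haplotypes, and recovered haplotypes are
    ranked by marginal log-likelihood. Includes a naive per-column variant
    caller, SAM/BAM and VCF ingestion, a seed-deterministic community read
    simulator for ground-truthed evaluation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
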