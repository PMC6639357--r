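Package: demethyl1
Title: Locus-Level Transposable Element Activation Analysis After Global
    DNA Demethylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for studying transcriptional activation of
    evolutionarily young LINE-1 retrotransposons after loss of DNA
    methylation in human neural progenitor cells. Provides locus-level
    transposable element expression quantification from uniquely mapped
    stranded paired-end alignments, per-element CpG methylation
    summarisation from bisulfite coverage files, classification of
    full-length intact L1s, detection of L1-gene fusion transcripts where
    an antisense L1 promoter drives a protein-coding gene, 50-kb proximity
    analysis of gene expression shifts, ChIP-seq metaprofiles anchored at
    element 5' ends, and CRISPR amplicon indel-diversity analysis. A
    synthetic-data module generates a miniature genome with age-stratified
    L1 copies and machine-readable ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    GenomeInfoDb,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    utils
Suggests:
    DESeq2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
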