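Package: exonhancer
Title: Enhancer-Activity Statistics for Conserved Coding Exons in Zebrafish
    Reporter Assays
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for calling tissue-specific enhancer
    activity of candidate sequences (conserved coding exons and noncoding
    elements) assayed by transient GFP reporter injection in zebrafish
    embryos. Converts controlled-vocabulary scoring transcripts into binary
    embryo-by-anatomy matrices, calls per-anatomy enhancer activity with a
    dual rule combining a one-sided two-proportion test against a
    minimal-promoter control with a shuffled-partition Wilcoxon rank-sum
    criterion, quantifies concurrent multi-anatomy activity with a
    co-regulation z statistic, matches enhancer anatomies against
    gene-expression annotation tables through an anatomy ontology with a
    random-gene permutation null, computes fourfold-degenerate-site
    conservation from pairwise coding alignments, and summarises
    ChIP-peak/exon interval overlaps with binomial standard errors. A
    synthetic-data generator with known ground truth emulates every input.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
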