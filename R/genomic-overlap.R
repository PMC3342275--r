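#' Genomic interval sets (BED semantics)
#'
#' All peak/exon analyses use BED conventions: 0-based half-open input
#' coordinates and strand-blind 1-bp-minimum overlap. Intervals are stored
#' as `GRanges` (converted to 1-based closed internally); abutting
#' half-open intervals never overlap.
#'
#' @param chrom chromosome names.
#' @param start,end 0-based half-open coordinates, `start < end`.
#' @param name,score,strand optional BED columns.
#' @return a `GRanges` with metadata columns `name` and `score`.
#' @export
genomic_intervals <- function(chrom, start, end, name = NULL, score = NULL,
                              strand = NULL) {
  if (any(start < 0) || any(start >= end))
    stopf("need 0 <= start < end for all intervals")
  if (any(!nzchar(chrom))) stopf("empty chromosome name")
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    strand = if (is.null(strand)) "*" else sub("^\\.$", "*", strand))
  S4Vectors::mcols(gr)$name <- if (is.null(name))
    paste0("iv", seq_along(gr)) else as.character(name)
  S4Vectors::mcols(gr)$score <- if (is.null(score)) NA_real_
  else as.numeric(score)
  gr
}

#' Read a BED3/BED6 file
#'
#' Thin wrapper around `rtracklayer::import`; the returned `GRanges` uses
#' the same internal convention as [genomic_intervals()].
#'
#' @param path BED file.
#' @return a `GRanges`.
#' @export
read_bed <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stopf("reading BED files requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(S4Vectors::mcols(gr)$name))
    S4Vectors::mcols(gr)$name <- paste0("iv", seq_along(gr))
  if (is.null(S4Vectors::mcols(gr)$score))
    S4Vectors::mcols(gr)$score <- NA_real_
  gr
}

#' @rdname read_bed
#' @param gr a `GRanges`.
#' @export
write_bed <- function(gr, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stopf("writing BED files requires the rtracklayer package")
  sc <- S4Vectors::mcols(gr)$score
  if (!is.null(sc) && anyNA(sc))
    S4Vectors::mcols(gr)$score <- NULL   # BED export forbids NA scores
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Per-interval overlap flags
#'
#' For each interval of `a`, whether it overlaps at least 1 bp of any
#' interval of `b` (same chromosome; strand ignored).
#'
#' @param a,b `GRanges`.
#' @return logical vector along `a`.
#' @export
intersect_any <- function(a, b) {
  # disjoint seqlevel sets are a legitimate "no overlap", not a user error
  suppressWarnings(IRanges::overlapsAny(a, b, ignore.strand = TRUE))
}

#' Binomial proportion with standard error
#'
#' @param k successes, `0 <= k <= n`.
#' @param n trials, `n >= 1`.
#' @return object of class `proportion_summary`: `k`, `n`, `fraction`,
#'   `sem` where `sem = sqrt(fraction (1 - fraction) / n)` (plug-in
#'   binomial standard error of the mean).
#' @export
proportion_summary <- function(k, n) {
  if (n < 1) stopf("n must be >= 1")
  if (k < 0 || k > n) stopf("need 0 <= k <= n")
  f <- k / n
  structure(list(k = as.integer(k), n = as.integer(n), fraction = f,
                 sem = binomial_sem(k, n)),
            class = "proportion_summary")
}

#' @export
print.proportion_summary <- function(x, ...) {
  cat(sprintf("%d/%d = %.1f%% +/- %.2g%% (s.e.m.)\n",
              x$k, x$n, 100 * x$fraction, 100 * x$sem))
  invisible(x)
}

#' Binomial standard error of the mean
#'
#' `sqrt((k/n) (1 - k/n) / n)`, the plug-in standard error of an observed
#' binomial fraction.
#'
#' @param k,n successes and trials.
#' @return numeric standard error.
#' @export
binomial_sem <- function(k, n) {
  if (any(n < 1)) stopf("n must be >= 1")
  p <- k / n
  sqrt(p * (1 - p) / n)
}

#' Fraction of features carrying a peak
#'
#' @param features,peaks `GRanges` (e.g. exons and H3K4me1 ChIP peaks).
#' @return a [proportion_summary()] over features.
#' @export
marked_fraction <- function(features, peaks) {
  if (length(features) == 0) stopf("empty feature set")
  proportion_summary(sum(intersect_any(features, peaks)), length(features))
}

#' Fraction of genes with at least one marked exon
#'
#' @param exons `GRanges` with a `gene` metadata column assigning each exon
#'   to exactly one gene id.
#' @param peaks `GRanges`.
#' @return a [proportion_summary()] over genes.
#' @export
genes_with_marked_exon <- function(exons, peaks) {
  gene <- S4Vectors::mcols(exons)$gene
  if (is.null(gene)) stopf("exons need a 'gene' metadata column")
  hit <- intersect_any(exons, peaks)
  marked <- tapply(hit, gene, any)
  proportion_summary(sum(marked), length(marked))
}

#' Size-matched intronic control regions
#'
#' For each target length, draws one sub-interval of that length placed
#' uniformly within a uniformly chosen intron long enough to hold it --
#' the background set for asking whether a chromatin mark prefers exons
#' over size-matched intronic sequence.
#'
#' @param introns `GRanges`.
#' @param target_lengths integer vector of control lengths (typically the
#'   exon lengths).
#' @param seed integer seed.
#' @return `GRanges` of controls, one per target length, in input order.
#' @export
intronic_controls <- function(introns, target_lengths, seed = 1L) {
  widths <- GenomicRanges::width(introns)
  with_seed(seed, {
    picks <- lapply(target_lengths, function(len) {
      ok <- which(widths >= len)
      if (length(ok) == 0)
        stopf("no intron of length >= %d available", len)
      i <- ok[sample.int(length(ok), 1)]
      off <- sample.int(widths[i] - len + 1L, 1) - 1L
      GenomicRanges::GRanges(
        seqnames = GenomicRanges::seqnames(introns)[i],
        ranges = IRanges::IRanges(
          start = GenomicRanges::start(introns)[i] + off, width = len))
    })
    ctrl <- do.call(c, picks)
    S4Vectors::mcols(ctrl)$name <- paste0("intronic_control",
                                          seq_along(ctrl))
    S4Vectors::mcols(ctrl)$score <- NA_real_
    ctrl
  })
}

#' Exons fully covered by a high-scoring TFBS cluster
#'
#' An exon counts only when a single cluster with score at or above
#' `min_score` contains it entirely (cluster start at or before the exon
#' start and cluster end at or after the exon end); a union of smaller
#' clusters does not qualify.
#'
#' @param exons `GRanges`.
#' @param clusters `GRanges` with a numeric `score` metadata column.
#' @param min_score minimum cluster score (default 500).
#' @return a [proportion_summary()] over exons.
#' @export
tfbs_full_coverage <- function(exons, clusters, min_score = 500) {
  sc <- S4Vectors::mcols(clusters)$score
  if (is.null(sc)) stopf("clusters need a 'score' metadata column")
  strong <- clusters[!is.na(sc) & sc >= min_score]
  covered <- IRanges::overlapsAny(exons, strong, type = "within",
                                  ignore.strand = TRUE)
  proportion_summary(sum(covered), length(exons))
}

# Exon preprocessing for the p300 analysis: exact duplicate records
# collapse to one retained copy; distinct records that overlap another
# record are removed (both of them); then the 3 bp..16 kbp length filter.
p300_preprocess_exons <- function(exons) {
  key <- paste(GenomicRanges::seqnames(exons),
               GenomicRanges::start(exons), GenomicRanges::end(exons))
  uniq <- exons[!duplicated(key)]
  hits <- GenomicRanges::countOverlaps(uniq, uniq, ignore.strand = TRUE)
  uniq <- uniq[hits == 1]   # only self-overlap
  w <- GenomicRanges::width(uniq)
  uniq[w >= 3 & w <= 16000]
}

#' Fraction of p300 peaks overlapping coding exons
#'
#' Exon annotations are cleaned first (see Details), then each peak is
#' tested for 1-bp overlap with any retained exon.
#'
#' Details: exact duplicate exon records collapse to a single copy;
#' partially overlapping distinct records are removed entirely; exons
#' shorter than 3 bp or longer than 16 kbp are dropped.
#'
#' @param peaks `GRanges` of ChIP peaks.
#' @param ccds_exons `GRanges` of coding exon annotations.
#' @return a [proportion_summary()] over peaks; attribute `retained_exons`
#'   carries the cleaned exon set.
#' @export
p300_exon_overlap <- function(peaks, ccds_exons) {
  kept <- p300_preprocess_exons(ccds_exons)
  out <- proportion_summary(sum(intersect_any(peaks, kept)), length(peaks))
  attr(out, "retained_exons") <- kept
  out
}

#' ESTs adjacent to (but not spanning) a flanked region
#'
#' Counts ESTs that intersect the window `[start - flank, end + flank)`
#' around a region without completely containing it. An EST spanning the
#' whole window is an ordinary overlapping transcript, not evidence of a
#' transcript boundary near the region, and is excluded.
#'
#' @param region a single-interval `GRanges`.
#' @param ests `GRanges` of EST alignments.
#' @param flank window extension in bp (default 1000).
#' @return integer count.
#' @export
est_adjacency <- function(region, ests, flank = 1000L) {
  if (flank < 0) stopf("flank must be non-negative")
  if (length(region) != 1) stopf("region must be a single interval")
  win <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(region),
    ranges = IRanges::IRanges(
      start = max(1L, GenomicRanges::start(region) - flank),
      end = GenomicRanges::end(region) + flank))
  inter <- intersect_any(ests, win)
  contains <- IRanges::overlapsAny(ests, win, type = "equal",
                                   ignore.strand = TRUE) |
    (GenomicRanges::seqnames(ests) ==
       as.character(GenomicRanges::seqnames(win)) &
       GenomicRanges::start(ests) <= GenomicRanges::start(win) &
       GenomicRanges::end(ests) >= GenomicRanges::end(win))
  sum(inter & !as.logical(contains))
}

#' Two-sided two-proportion comparison
#'
#' Continuity-corrected chi-squared two-proportion test, two-sided; used
#' for cohort-level comparisons (e.g. coding vs noncoding enhancer rates).
#'
#' @param k1,n1,k2,n2 successes and totals of the two cohorts.
#' @return p-value.
#' @export
two_proportion_compare <- function(k1, n1, k2, n2) {
  if (n1 < 1 || n2 < 1) stopf("zero-size group")
  suppressWarnings(
    stats::prop.test(c(k1, k2), c(n1, n2), correct = TRUE)$p.value)
}
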