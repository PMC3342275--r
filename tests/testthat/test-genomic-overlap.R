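test_that("1-bp overlap and half-open abutment behave as in BED semantics", {
  a <- genomic_intervals("chr1", 100, 200)
  expect_true(intersect_any(a, genomic_intervals("chr1", 199, 300)))
  expect_false(intersect_any(a, genomic_intervals("chr1", 200, 300)))
  expect_false(intersect_any(a, genomic_intervals("chr2", 100, 200)))
  expect_error(genomic_intervals("chr1", 200, 200), "start < end")
  expect_error(genomic_intervals("chr1", -1, 5), "start < end|0 <=")
  expect_error(genomic_intervals("", 0, 5), "chromosome")
})

test_that("overlap flags equal the brute-force all-pairs oracle and are shift-invariant", {
  for (s in 1:20) {
    a <- random_bed(150, seed = s)
    b <- random_bed(120, seed = s + 1000)
    got <- intersect_any(bed_to_gr(a), bed_to_gr(b))
    expect_equal(got, oracle_overlap_flags(a, b))
    # translating every interval by +c changes nothing
    a2 <- a; a2$start <- a$start + 7917L; a2$end <- a$end + 7917L
    b2 <- b; b2$start <- b$start + 7917L; b2$end <- b$end + 7917L
    expect_equal(intersect_any(bed_to_gr(a2), bed_to_gr(b2)), got)
  }
})

test_that("marked fraction carries the binomial s.e.m. and is monotone in peaks", {
  si <- simulate_intervals(24, 40, planted_fraction = 0.375, seed = 2)
  mf <- marked_fraction(si$features, si$peaks)
  expect_equal(mf$k, 9)
  expect_equal(mf$n, 24)
  expect_equal(mf$sem, sqrt(0.375 * 0.625 / 24))
  none <- marked_fraction(si$features,
                          genomic_intervals("chrZ", 0, 10))
  expect_equal(none$fraction, 0)
  expect_equal(none$sem, 0)
  expect_error(marked_fraction(si$features[0], si$peaks), "empty")
  # adding peaks never decreases k
  more <- c(si$peaks, genomic_intervals("chrS", 10, 400))
  expect_gte(marked_fraction(si$features, more)$k, mf$k)
})

test_that("gene-level marking counts each gene once", {
  # 100 toy genes x 3 exons; plant peaks on one exon of 63 genes
  exon_start <- as.integer(outer(0:2 * 1000, 0:99 * 10000, `+`))
  exons <- genomic_intervals("chr1", exon_start, exon_start + 150)
  S4Vectors::mcols(exons)$gene <- rep(paste0("g", sprintf("%02d", 1:100)),
                                      each = 3)
  set.seed(5)
  marked_genes <- sort(sample(100, 63))
  peak_start <- (marked_genes - 1L) * 10000L + 50L
  peaks <- genomic_intervals("chr1", peak_start, peak_start + 40)
  pg <- genes_with_marked_exon(exons, peaks)
  expect_equal(pg$k, 63)
  expect_equal(pg$n, 100)
  # a peak spanning several exons of one gene still counts the gene once
  big <- genomic_intervals("chr1", 0, 3000)
  expect_equal(genes_with_marked_exon(exons, big)$k, 1)
  # brute-force gene tally on random fixtures
  for (s in 1:10) {
    d <- random_bed(80, seed = s)
    g <- paste0("g", sample(1:25, 80, replace = TRUE))
    pk <- random_bed(40, seed = s + 500)
    ex <- bed_to_gr(d); S4Vectors::mcols(ex)$gene <- g
    want <- tapply(oracle_overlap_flags(d, pk), g, any)
    got <- genes_with_marked_exon(ex, bed_to_gr(pk))
    expect_equal(got$k, sum(want))
    expect_equal(got$n, length(want))
  }
})

test_that("intronic controls are size-matched, in-bounds, deterministic and uniform", {
  introns <- genomic_intervals(c("chr1", "chr1"), c(0, 5000),
                               c(1000, 5400))
  lens <- c(100L, 250L, 399L)
  ctrl <- intronic_controls(introns, lens, seed = 4)
  expect_equal(GenomicRanges::width(ctrl), lens)
  for (i in seq_along(ctrl)) {
    inside <- IRanges::overlapsAny(ctrl[i], introns, type = "within")
    expect_true(inside)
  }
  expect_identical(GenomicRanges::start(intronic_controls(introns, lens,
                                                          seed = 4)),
                   GenomicRanges::start(ctrl))
  expect_error(intronic_controls(introns, 2000L, seed = 1),
               "no intron of length")
  # uniform placement within a single intron (chi-squared GOF)
  one <- genomic_intervals("chr1", 0, 120)
  starts <- vapply(1:2000, function(s)
    GenomicRanges::start(intronic_controls(one, 20L, seed = s)), 0L)
  # possible 0-based starts 0..100 -> 1-based 1..101; bin into 10 groups
  bins <- cut(starts, breaks = seq(0.5, 101.5, length.out = 11))
  expect_gt(chisq.test(table(bins))$p.value, 0.001)
})

test_that("TFBS full coverage needs a single high-scoring containing cluster", {
  exon <- genomic_intervals("chr1", 100, 200)
  exact <- genomic_intervals("chr1", 100, 200, score = 500)
  expect_equal(tfbs_full_coverage(exon, exact)$k, 1)   # boundary inclusive
  low <- genomic_intervals("chr1", 100, 200, score = 499)
  expect_equal(tfbs_full_coverage(exon, low)$k, 0)
  halves <- genomic_intervals(c("chr1", "chr1"), c(90, 150), c(151, 260),
                              score = c(900, 900))
  expect_equal(tfbs_full_coverage(exon, halves)$k, 0)  # union insufficient
  wider <- genomic_intervals("chr1", 50, 300, score = 700)
  expect_equal(tfbs_full_coverage(exon, wider)$k, 1)
})

test_that("p300 exon preprocessing and peak overlap follow the cleaning rules", {
  exons <- genomic_intervals(
    rep("chr1", 6),
    c(100, 100, 500, 550, 900, 2000),
    c(200, 200, 600, 620, 901, 19000))
  kept <- exonhancer:::p300_preprocess_exons(exons)
  # duplicates at 100-200 collapse to one retained copy; 500-600 and
  # 550-620 overlap each other and are both removed; 900-901 is < 3 bp;
  # 2000-19000 is > 16 kbp
  expect_equal(GenomicRanges::start(kept), 101)
  peaks <- genomic_intervals(rep("chr1", 3), c(150, 560, 5000),
                             c(160, 580, 5100))
  res <- p300_exon_overlap(peaks, exons)
  expect_equal(res$k, 1)    # only the peak on the retained duplicate
  expect_equal(res$n, 3)
  # planted-fraction fixture mirrors the published 3.3% structure
  si <- simulate_intervals(1000, 1000, planted_fraction = 0.033, seed = 9)
  frac <- p300_exon_overlap(si$peaks, si$features)
  expect_equal(frac$k, 33)
})

test_that("EST adjacency counts window-intersecting but not window-spanning ESTs", {
  region <- genomic_intervals("chr1", 5000, 5200)
  # window is [4000, 6200)
  spanning <- genomic_intervals("chr1", 3000, 7000)
  expect_equal(est_adjacency(region, spanning), 0)
  left <- genomic_intervals("chr1", 3900, 4100)
  expect_equal(est_adjacency(region, left), 1)
  outside <- genomic_intervals("chr1", 7000, 7500)
  expect_equal(est_adjacency(region, outside), 0)
  exact <- genomic_intervals("chr1", 4000, 6200)   # equals the window
  expect_equal(est_adjacency(region, exact), 0)
  expect_error(est_adjacency(region, left, flank = -5), "non-negative")
  # brute force on random EST fixtures
  for (s in 1:10) {
    ests <- random_bed(100, max_pos = 12000, max_len = 4000, n_chrom = 1,
                       seed = s)
    want <- sum(ests$chrom == "chr1" &
                  pmax(ests$start, 4000) < pmin(ests$end, 6200) &
                  !(ests$start <= 4000 & ests$end >= 6200))
    expect_equal(est_adjacency(region, bed_to_gr(ests)), want)
  }
})

test_that("BED files round-trip through the reader with BED coordinates", {
  d <- random_bed(25, seed = 41)
  gr <- bed_to_gr(d)
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(gr, path)
  back <- read_bed(path)
  expect_equal(gr_to_bed(back), d, ignore_attr = TRUE)
})

test_that("binomial s.e.m. reproduces the published uncertainty values", {
  expect_equal(round(100 * binomial_sem(37, 358), 1), 1.6)
  expect_equal(round(100 * binomial_sem(8874, 110461), 2), 0.08)
  expect_equal(round(100 * binomial_sem(517, 813), 1), 1.7)
  expect_equal(binomial_sem(0, 50), 0)
  expect_equal(binomial_sem(50, 100), 0.05)
  # closed form to machine precision across magnitudes
  set.seed(31)
  for (i in 1:50) {
    n <- sample.int(1e6, 1); k <- sample.int(n, 1)
    p <- k / n
    expect_identical(binomial_sem(k, n), sqrt(p * (1 - p) / n))
  }
  expect_error(binomial_sem(1, 0), ">= 1")
})

test_that("two-sided cohort comparison matches the chi-squared oracle", {
  expect_gt(two_proportion_compare(30, 100, 30, 100), 0.9)
  expect_gt(two_proportion_compare(24, 31, 105, 147), 0.05)
  set.seed(13)
  for (i in 1:100) {
    n1 <- sample(5:300, 1); n2 <- sample(5:300, 1)
    k1 <- rbinom(1, n1, runif(1)); k2 <- rbinom(1, n2, runif(1))
    expect_equal(two_proportion_compare(k1, n1, k2, n2),
                 oracle_prop_twosided(k1, n1, k2, n2), tolerance = 1e-9)
  }
})
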