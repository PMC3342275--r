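test_that("percent identity excludes gap and N columns and is symmetric", {
  same <- aligned_cds_pair(strrep("ACG", 100), strrep("ACG", 100))
  expect_equal(percent_identity(same)$identity, 1.0)

  pr <- aligned_cds_pair("ACG-T", "AAGCT")
  r <- percent_identity(pr)
  expect_equal(r$identity, 0.75)          # gap column excluded
  expect_equal(r$n_compared_columns, 4)

  # N columns excluded from the denominator, never matching
  pn <- aligned_cds_pair("ANGT", "ANGT")
  expect_equal(percent_identity(pn)$n_compared_columns, 3)
  expect_equal(percent_identity(pn)$identity, 1.0)

  expect_error(percent_identity(aligned_cds_pair("A-G", "-C-")),
               "no gap-free")
  expect_error(aligned_cds_pair("A-G", "A-G"), "gapped in both")

  # symmetry and brute-force column-scan oracle on random gapped pairs
  set.seed(17)
  nts <- c("A", "C", "G", "T", "N")
  for (i in 1:100) {
    n <- sample(30:90, 1)
    a <- sample(nts, n, replace = TRUE, prob = c(rep(0.24, 4), 0.04))
    b <- sample(nts, n, replace = TRUE, prob = c(rep(0.24, 4), 0.04))
    gap <- sample(n, round(0.1 * n))
    a[gap[seq_len(length(gap) %/% 2)]] <- "-"
    b[gap[-seq_len(length(gap) %/% 2)]] <- "-"
    sa <- paste(a, collapse = ""); sb <- paste(b, collapse = "")
    pair <- aligned_cds_pair(sa, sb)
    got <- percent_identity(pair)
    want <- oracle_identity(sa, sb)
    expect_equal(got$identity, unname(want["identity"]))
    expect_equal(got$n_compared_columns, unname(want["n"]))
    expect_equal(percent_identity(aligned_cds_pair(sb, sa))$identity,
                 got$identity)
  }
})

test_that("the fourfold prefix table matches the standard genetic code", {
  expect_setequal(exonhancer:::FOURFOLD_PREFIXES, oracle_fourfold_prefixes())
})

test_that("fourfold site extraction requires whole aligned codons with a shared fourfold prefix", {
  # Ala (GC*) third position A vs G: one qualifying site
  s <- fourfold_sites(aligned_cds_pair("GCA", "GCG"))
  expect_equal(nrow(s), 1)
  expect_false(s$conserved)
  # Leu TT* is twofold: not a qualifying site
  expect_equal(nrow(fourfold_sites(aligned_cds_pair("TTA", "TTG"))), 0)
  # differing prefixes disqualify even when both are fourfold families
  expect_equal(nrow(fourfold_sites(aligned_cds_pair("GCA", "GGA"))), 0)
  # codons containing N or a gap are excluded
  expect_equal(nrow(fourfold_sites(aligned_cds_pair("GCN", "GCA"))), 0)
  # whole-codon gaps: only the gap-free codon qualifies
  expect_equal(nrow(fourfold_sites(aligned_cds_pair("GCAGCC", "---GCC"))), 1)

  # counts match a brute-force scan over simulated in-frame alignments
  oracle_pre <- oracle_fourfold_prefixes()
  for (s in 1:20) {
    pair <- simulate_cds_pair(60, id_fourfold = 0.5, gap_rate = 0.05,
                              seed = s)
    a <- paste(pair$seq_a, collapse = ""); b <- paste(pair$seq_b, collapse = "")
    # gap-free codon columns (gaps are whole codons here)
    n4 <- 0; cons <- 0
    for (i in seq(1, nchar(a) - 2, by = 3)) {
      ca <- substr(a, i, i + 2); cb <- substr(b, i, i + 2)
      if (grepl("-", ca) || grepl("-", cb)) next
      if (substr(ca, 1, 2) == substr(cb, 1, 2) &&
          substr(ca, 1, 2) %in% oracle_pre) {
        n4 <- n4 + 1
        cons <- cons + (substr(ca, 3, 3) == substr(cb, 3, 3))
      }
    }
    sites <- fourfold_sites(pair)
    expect_equal(nrow(sites), n4)
    expect_equal(sum(sites$conserved), cons)
  }
})

test_that("frame offsets shift the codon grid correctly", {
  # two leading partial-codon bases, then GCA GCA vs GCA GCG
  pair <- aligned_cds_pair("ATGCAGCA", "ATGCAGCG", frame_offset = 2L)
  s <- fourfold_sites(pair)
  expect_equal(nrow(s), 2)          # both Ala codons qualify
  expect_equal(sum(s$conserved), 1) # third positions A/A then A/G
  # at frame 0 the same columns parse as ATG CAG CA. -> no fourfold site
  expect_equal(nrow(fourfold_sites(
    aligned_cds_pair("ATGCAGCA", "ATGCAGCG", frame_offset = 0L))), 0)
})

test_that("fourfold p-distance applies the minimum-codon rule", {
  # 10 qualifying Ala codons, all conserved
  p10 <- aligned_cds_pair(strrep("GCA", 10), strrep("GCA", 10))
  expect_equal(fourfold_p_distance(p10), 1.0, ignore_attr = TRUE)
  # 4 qualifying codons: undefined
  p4 <- aligned_cds_pair(strrep("GCA", 4), strrep("GCA", 4))
  expect_true(is.na(fourfold_p_distance(p4)))
  expect_equal(attr(fourfold_p_distance(p4), "n_fourfold_codons"), 4)
  # 5 qualifying codons: defined (boundary)
  p5 <- aligned_cds_pair(strrep("GCA", 5), strrep("GCA", 5))
  expect_false(is.na(fourfold_p_distance(p5)))
  # 8 qualifying, 6 identical -> 0.75
  a <- strrep("GGA", 8)
  b <- paste0(strrep("GGA", 6), strrep("GGC", 2))
  expect_equal(fourfold_p_distance(aligned_cds_pair(a, b)), 0.75,
               ignore_attr = TRUE)
})

test_that("the statistic ignores silent changes at non-qualifying codons", {
  pair <- simulate_cds_pair(80, id_fourfold = 0.6, seed = 5)
  base <- fourfold_p_distance(pair)
  # flip every twofold third position to its synonymous partner in seq B
  twofold_swap <- c(A = "G", G = "A", T = "C", C = "T")
  sb <- pair$seq_b
  for (i in seq(1, length(sb) - 2, by = 3)) {
    pre <- paste(sb[i:(i + 1)], collapse = "")
    if (!(pre %in% exonhancer:::FOURFOLD_PREFIXES) &&
        pre %in% c("TT", "AA", "GA", "CA"))
      sb[i + 2] <- twofold_swap[[sb[i + 2]]]
  }
  mut <- aligned_cds_pair(paste(pair$seq_a, collapse = ""),
                          paste(sb, collapse = ""))
  expect_equal(fourfold_p_distance(mut), base, ignore_attr = TRUE)
})

test_that("planted fourfold-site identity is recovered", {
  for (s in 1:10) {
    pair <- simulate_cds_pair(200, id_fourfold = 0.5, seed = s)
    est <- fourfold_p_distance(pair)
    n4 <- attr(est, "n_fourfold_codons")
    expect_lt(abs(est - 0.5), 3 * sqrt(0.25 / n4) + 1e-9)
  }
})

test_that("candidate filter reports all violated criteria", {
  dev_seq <- strrep("GATTACAGGA", 20)      # 200 bp, no cut sites
  ok <- cce_candidate_filter(dev_seq, identity = 0.79,
                             developmental = TRUE)
  expect_true(ok$pass)
  expect_length(ok$reasons, 0)
  cut <- cce_candidate_filter(paste0(dev_seq, "CTCGAG"), 0.79, TRUE)
  expect_false(cut$pass)
  expect_equal(cut$reasons, "restriction-site")
  short <- cce_candidate_filter(strrep("GATTACAGGA", 9), 0.90, TRUE)
  expect_false(short$pass)            # 90 bp < 100
  expect_equal(short$reasons, "length")
  multi <- cce_candidate_filter(paste0(strrep("A", 50), "AGATCT"), 0.5,
                                FALSE)
  expect_setequal(multi$reasons,
                  c("conservation", "length", "restriction-site",
                    "not-developmental"))
  # monotone in identity: raising identity never flips pass to fail
  expect_true(cce_candidate_filter(dev_seq, 0.61, TRUE)$pass)
  expect_false(cce_candidate_filter(dev_seq, 0.60, TRUE)$pass)  # strict >
})

test_that("aligned FASTA pairs round-trip through the reader", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">zebrafish frame=0", "GCAGCT--TAAA",
               ">human", "GCGGCTGG--AA"), path)
  pair <- read_aligned_pair(path)
  expect_s3_class(pair, "aligned_cds_pair")
  expect_equal(pair$frame_offset, 0L)
  expect_equal(length(pair$seq_a), 12)
  writeLines(c(">only", "ACGT"), path)
  expect_error(read_aligned_pair(path), "2 FASTA records")
})
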