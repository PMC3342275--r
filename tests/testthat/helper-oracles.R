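# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles deliberately avoid the code paths they check.

# Textbook continuity-corrected chi-squared two-proportion test, one-sided
# (group 1 greater): build the 2x2 table, expected counts from margins,
# Yates correction capped at the observed deviation, signed-z tail.
oracle_prop_greater <- function(k1, n1, k0, n0) {
  x <- rbind(c(k1, n1 - k1), c(k0, n0 - k0))
  e <- outer(rowSums(x), colSums(x)) / sum(x)
  y <- min(0.5, abs(x[1, 1] - e[1, 1]))
  stat <- sum((abs(x - e) - y)^2 / e)
  z <- sign(k1 / n1 - k0 / n0) * sqrt(stat)
  pnorm(z, lower.tail = FALSE)
}

oracle_prop_twosided <- function(k1, n1, k2, n2) {
  x <- rbind(c(k1, n1 - k1), c(k2, n2 - k2))
  e <- outer(rowSums(x), colSums(x)) / sum(x)
  y <- min(0.5, abs(x[1, 1] - e[1, 1]))
  stat <- sum((abs(x - e) - y)^2 / e)
  pchisq(stat, df = 1, lower.tail = FALSE)
}

# All-pairs interval overlap scan on plain data frames (0-based half-open).
oracle_overlap_flags <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] &
          pmax(b$start, a$start[i]) < pmin(b$end, a$end[i]))
  }, FALSE)
}

# Convert a GRanges back to 0-based half-open columns for the oracle.
gr_to_bed <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

random_bed <- function(n, max_pos = 5000, max_len = 120, n_chrom = 2,
                       seed = 1) {
  set.seed(seed)
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  data.frame(chrom = paste0("chr", sample.int(n_chrom, n, replace = TRUE)),
             start = start,
             end = start + sample.int(max_len, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

bed_to_gr <- function(d, score = NULL) {
  genomic_intervals(d$chrom, d$start, d$end, score = score)
}

# Fourfold-degenerate dinucleotide prefixes derived independently from the
# standard genetic code (a prefix qualifies iff all four completions encode
# one amino acid).
oracle_fourfold_prefixes <- function() {
  gc <- Biostrings::GENETIC_CODE
  pre <- unique(substr(names(gc), 1, 2))
  pre[vapply(pre, function(p) {
    aa <- gc[paste0(p, c("A", "C", "G", "T"))]
    length(unique(aa)) == 1
  }, FALSE)]
}

# Column-scan identity oracle: gap-free, N-free columns only.
oracle_identity <- function(sa, sb) {
  a <- strsplit(sa, "")[[1]]; b <- strsplit(sb, "")[[1]]
  keep <- a != "-" & b != "-" & a != "N" & b != "N"
  c(identity = mean(a[keep] == b[keep]), n = sum(keep))
}

# Toy forebrain-style ontology: one seed with `n_children` children, each
# child with one grandchild (to check the expansion stops at one level).
toy_ontology <- function(n_children = 5) {
  seeds <- data.frame(term_id = "ZFA:F", name = "forebrain",
                      parent_id = NA_character_)
  kids <- data.frame(term_id = paste0("ZFA:F", seq_len(n_children)),
                     name = paste0("forebrain child ", seq_len(n_children)),
                     parent_id = "ZFA:F")
  grand <- data.frame(term_id = paste0("ZFA:FG", seq_len(n_children)),
                      name = paste0("grandchild ", seq_len(n_children)),
                      parent_id = paste0("ZFA:F", seq_len(n_children)))
  ontology(rbind(seeds, kids, grand))
}

random_expression_matrix <- function(n = 30, p = 0.3, seed = 1,
                                     construct_id = "rand") {
  simulate_embryos(embryo_sim_spec(n, rep(p, 10), seed = seed),
                   construct_id = construct_id)
}
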