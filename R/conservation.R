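#' Pairwise aligned coding sequences
#'
#' Container for a pairwise CDS alignment between two species (e.g.
#' zebrafish and human): two equal-length aligned nucleotide strings over
#' A,C,G,T,N,- and a codon frame offset giving the phase of the first
#' aligned column (0 = the first ungapped base of each sequence starts a
#' codon). Columns gapped in both sequences are disallowed.
#'
#' @param seq_a,seq_b aligned sequences (single strings).
#' @param frame_offset 0, 1 or 2: number of bases of a partial codon before
#'   the first complete codon in each ungapped sequence.
#' @return an object of class `aligned_cds_pair`.
#' @export
aligned_cds_pair <- function(seq_a, seq_b, frame_offset = 0L) {
  a <- toupper(seq_a); b <- toupper(seq_b)
  if (nchar(a) != nchar(b)) stopf("aligned sequences differ in length")
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  ok <- c("A", "C", "G", "T", "N", "-")
  if (!all(ca %in% ok) || !all(cb %in% ok))
    stopf("sequences may contain only A,C,G,T,N,-")
  if (any(ca == "-" & cb == "-"))
    stopf("columns gapped in both sequences are not allowed")
  if (!frame_offset %in% 0:2) stopf("frame_offset must be 0, 1 or 2")
  structure(list(seq_a = ca, seq_b = cb,
                 frame_offset = as.integer(frame_offset)),
            class = "aligned_cds_pair")
}

#' Read a pairwise aligned FASTA
#'
#' Expects exactly two records of equal aligned length; an optional
#' `frame=<0|1|2>` token in the first record's description sets the frame
#' offset.
#'
#' @param path FASTA file.
#' @return an [aligned_cds_pair()].
#' @export
read_aligned_pair <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) != 2) stopf("expected exactly 2 FASTA records, got %d",
                             length(ss))
  fr <- regmatches(names(ss)[1], regexpr("frame=[0-2]", names(ss)[1]))
  frame <- if (length(fr)) as.integer(sub("frame=", "", fr)) else 0L
  aligned_cds_pair(as.character(ss[[1]]), as.character(ss[[2]]), frame)
}

#' Gap-free percent identity
#'
#' Identity over alignment columns where neither species has a gap; columns
#' containing N in either sequence are excluded from the denominator as
#' well (ambiguity is not penalised), and N never matches.
#'
#' @param pair an [aligned_cds_pair()].
#' @return list with `identity` and `n_compared_columns`.
#' @export
percent_identity <- function(pair) {
  cmp <- pair$seq_a != "-" & pair$seq_b != "-" &
    pair$seq_a != "N" & pair$seq_b != "N"
  if (!any(cmp)) stopf("no gap-free comparable columns in the alignment")
  list(identity = mean(pair$seq_a[cmp] == pair$seq_b[cmp]),
       n_compared_columns = sum(cmp))
}

# Dinucleotide prefixes whose codon family is fourfold degenerate under the
# standard genetic code.
FOURFOLD_PREFIXES <- c("GC", "GG", "CC", "AC", "GT", "CT", "TC", "CG")

# Enumerate aligned codons: whole-codon gap-free triples of columns that are
# in frame for BOTH ungapped sequences. Returns a data frame of codon
# strings and the index of the third-position column.
aligned_codons <- function(pair) {
  n <- length(pair$seq_a)
  posa <- cumsum(pair$seq_a != "-")   # ungapped index in seq A per column
  posb <- cumsum(pair$seq_b != "-")
  f <- pair$frame_offset
  starts <- which(
    seq_len(n) <= n - 2 &
      pair$seq_a != "-" & pair$seq_b != "-" &
      (posa - 1 - f) %% 3 == 0 & (posb - 1 - f) %% 3 == 0)
  keep <- starts[vapply(starts, function(i) {
    all(pair$seq_a[i:(i + 2)] != "-") && all(pair$seq_b[i:(i + 2)] != "-")
  }, FALSE)]
  if (length(keep) == 0)
    return(data.frame(codon_a = character(), codon_b = character(),
                      third_col = integer()))
  data.frame(
    codon_a = vapply(keep, function(i) paste(pair$seq_a[i:(i + 2)],
                                             collapse = ""), ""),
    codon_b = vapply(keep, function(i) paste(pair$seq_b[i:(i + 2)],
                                             collapse = ""), ""),
    third_col = keep + 2L, stringsAsFactors = FALSE)
}

#' Aligned fourfold-degenerate third-position sites
#'
#' A site qualifies when both species have a whole, gap-free, in-frame
#' codon at the aligned position, the codons agree at positions 1--2, and
#' that shared dinucleotide prefix defines a fourfold-degenerate codon
#' family (GC*, GG*, CC*, AC*, GT*, CT*, TC*, CG*). Codons containing N are
#' excluded. At such sites any third-position nucleotide is synonymous in
#' both species, so their conservation reflects selection beyond the
#' protein.
#'
#' @param pair an [aligned_cds_pair()].
#' @return data frame with `prefix`, `third_a`, `third_b`, `conserved`.
#' @export
fourfold_sites <- function(pair) {
  cod <- aligned_codons(pair)
  if (nrow(cod) == 0)
    return(data.frame(prefix = character(), third_a = character(),
                      third_b = character(), conserved = logical()))
  pa <- substr(cod$codon_a, 1, 2); pb <- substr(cod$codon_b, 1, 2)
  ok <- pa == pb & pa %in% FOURFOLD_PREFIXES &
    !grepl("N", cod$codon_a) & !grepl("N", cod$codon_b)
  cod <- cod[ok, , drop = FALSE]
  data.frame(prefix = substr(cod$codon_a, 1, 2),
             third_a = substr(cod$codon_a, 3, 3),
             third_b = substr(cod$codon_b, 3, 3),
             conserved = substr(cod$codon_a, 3, 3) ==
               substr(cod$codon_b, 3, 3),
             stringsAsFactors = FALSE)
}

#' Fourfold-site conservation (p-distance convention)
#'
#' The conserved-site fraction over qualifying fourfold third positions:
#' number of conserved sites divided by total qualifying sites. Undefined
#' (NA, with attribute `n_fourfold_codons`) when fewer than `min_codons`
#' codons qualify -- too few silent sites to estimate conservation.
#'
#' @param pair an [aligned_cds_pair()].
#' @param min_codons minimum qualifying codons (default 5).
#' @return conserved fraction, or NA when under `min_codons`; attribute
#'   `n_fourfold_codons` carries the qualifying count.
#' @export
fourfold_p_distance <- function(pair, min_codons = 5L) {
  sites <- fourfold_sites(pair)
  val <- if (nrow(sites) < min_codons) NA_real_ else mean(sites$conserved)
  attr(val, "n_fourfold_codons") <- nrow(sites)
  val
}

#' Candidate filter for conserved coding elements
#'
#' A coding exon qualifies as a testable candidate when its zebrafish-human
#' identity exceeds `min_identity`, its length lies in
#' `[min_length, max_length]`, its (unaligned) sequence contains neither
#' the XhoI (CTCGAG) nor the BglII (AGATCT) recognition site (both sites
#' are their own reverse complements, so a forward-strand scan suffices),
#' and its gene is flagged developmental. Failures list every violated
#' criterion.
#'
#' @param sequence unaligned exon nucleotide sequence.
#' @param identity zebrafish-human percent identity (fraction).
#' @param developmental logical gene flag.
#' @param min_identity,min_length,max_length filter bounds (defaults 0.60,
#'   100, 1000).
#' @return list with `pass` and `reasons` (character vector, empty on pass).
#' @export
cce_candidate_filter <- function(sequence, identity, developmental,
                                 min_identity = 0.60, min_length = 100L,
                                 max_length = 1000L) {
  sequence <- toupper(sequence)
  len <- nchar(sequence)
  reasons <- character()
  if (!(identity > min_identity))
    reasons <- c(reasons, "conservation")
  if (len < min_length || len > max_length)
    reasons <- c(reasons, "length")
  if (grepl("CTCGAG", sequence, fixed = TRUE) ||
      grepl("AGATCT", sequence, fixed = TRUE))
    reasons <- c(reasons, "restriction-site")
  if (!isTRUE(developmental))
    reasons <- c(reasons, "not-developmental")
  list(pass = length(reasons) == 0, reasons = reasons)
}
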