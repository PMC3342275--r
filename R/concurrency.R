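#' Joint activity counts for a pair of anatomies
#'
#' Tabulates, per embryo, the four joint activity patterns 00, 01, 10, 11
#' for two anatomies. Transient transgenesis is mosaic, so an enhancer
#' active in two tissues need not light both up in every embryo; these
#' counts are what separates genuine concurrent activity from mosaicism.
#'
#' @param m an [expression_matrix()].
#' @param a,b distinct anatomy names or codes.
#' @return list with `anatomy_a`, `anatomy_b`, `N00`, `N01`, `N10`, `N11`,
#'   `N_total`.
#' @export
pair_counts <- function(m, a, b) {
  ia <- resolve_anatomy(m, a); ib <- resolve_anatomy(m, b)
  if (ia == ib) stopf("pair must name two distinct anatomies")
  xa <- m$data[, ia]; xb <- m$data[, ib]
  list(anatomy_a = m$vocabulary$name[ia], anatomy_b = m$vocabulary$name[ib],
       N00 = sum(xa == 0 & xb == 0), N01 = sum(xa == 0 & xb == 1),
       N10 = sum(xa == 1 & xb == 0), N11 = sum(xa == 1 & xb == 1),
       N_total = length(xa))
}

#' Co-regulation z statistic for concurrent activity
#'
#' Under a null of equal probability 1/4 for each of the four joint
#' patterns, the number of doubly-active embryos N11 is Binomial(N, 1/4);
#' the statistic is its normal standardisation
#' z = (N11 - 0.25 N) / sqrt(N * 0.25 * 0.75), with a one-sided upper-tail
#' normal p-value (enrichment of concurrent activity only). Note the null
#' is the stated four-cases-equal hypothesis, not independence of the two
#' margins: with marginal rates far from 0.5 the statistic is deliberately
#' sensitive to overall activity, which is why only large z (> 3) is
#' highlighted in reporting.
#'
#' @param counts output of [pair_counts()].
#' @return list with `z`, `p`, `pair`.
#' @export
concurrency_z <- function(counts) {
  n <- counts$N_total
  if (n < 1) stopf("empty pair counts")
  z <- (counts$N11 - 0.25 * n) / sqrt(n * 0.25 * 0.75)
  list(z = z, p = stats::pnorm(z, lower.tail = FALSE),
       pair = c(counts$anatomy_a, counts$anatomy_b))
}

#' Concurrency screen over all anatomy pairs
#'
#' Evaluates the co-regulation z statistic for every unordered pair of
#' anatomies (45 pairs for the default 10-region vocabulary), in
#' lexicographic code order, flagging pairs at `p < alpha`. No
#' multiple-testing correction is applied by default; `bonferroni = TRUE`
#' divides alpha by the number of pairs.
#'
#' @param m an [expression_matrix()].
#' @param alpha flagging level (default 0.05).
#' @param bonferroni apply Bonferroni correction across pairs.
#' @param anatomies optional subset of anatomy names to restrict the screen
#'   (e.g. the significant anatomies of an [enhancer_call()]).
#' @return data frame: `anatomy_a`, `anatomy_b`, `N00`..`N11`, `z`, `p`,
#'   `flagged`, plus `highlight` marking z > 3.
#' @export
concurrency_pairs <- function(m, alpha = 0.05, bonferroni = FALSE,
                              anatomies = NULL) {
  if (n_embryos(m) < 1) stopf("empty expression matrix")
  idx <- if (is.null(anatomies)) seq_len(ncol(m$data))
  else sort(vapply(anatomies, function(a) resolve_anatomy(m, a), 0L))
  if (length(idx) < 2) stopf("need at least two anatomies")
  pairs <- utils::combn(idx, 2)
  thr <- if (bonferroni) alpha / ncol(pairs) else alpha
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    pc <- pair_counts(m, pairs[1, j], pairs[2, j])
    cz <- concurrency_z(pc)
    data.frame(anatomy_a = pc$anatomy_a, anatomy_b = pc$anatomy_b,
               N00 = pc$N00, N01 = pc$N01, N10 = pc$N10, N11 = pc$N11,
               z = cz$z, p = cz$p, flagged = cz$p < thr,
               highlight = cz$z > 3, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
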