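#' Per-anatomy expressing proportions
#'
#' Fraction of surviving embryos with expression in each anatomy: column
#' sums of the binary matrix divided by the number of scored embryos.
#'
#' @param m an [expression_matrix()] with at least one embryo.
#' @return data frame with columns `anatomy`, `k` (expressing embryos),
#'   `n` (total embryos), `p_hat`.
#' @export
expression_proportions <- function(m) {
  if (n_embryos(m) < 1) stopf("expression matrix has no embryos")
  k <- as.integer(colSums(m$data))
  data.frame(anatomy = m$vocabulary$name, k = k, n = n_embryos(m),
             p_hat = k / n_embryos(m), stringsAsFactors = FALSE)
}

#' One-sided two-proportion test against the control
#'
#' Tests whether the fraction of embryos expressing under the candidate
#' construct exceeds the control fraction, using the continuity-corrected
#' chi-squared two-sample proportion test (`stats::prop.test`) with
#' alternative "greater". Where the candidate proportion is at or below the
#' control, the one-sided p-value is near 1 -- matching the behaviour
#' required of the calling rule.
#'
#' @param k1,n1 expressing / total embryo counts for the candidate.
#' @param k0,n0 counts for the minimal-promoter control.
#' @return p-value in \[0, 1\].
#' @export
proportions_test <- function(k1, n1, k0, n0) {
  if (n1 < 1 || n0 < 1) stopf("zero-size group in proportions test")
  if (k1 < 0 || k1 > n1 || k0 < 0 || k0 > n0) stopf("invalid counts")
  p <- suppressWarnings(
    stats::prop.test(c(k1, k0), c(n1, n0), alternative = "greater",
                     correct = TRUE)$p.value)
  min(max(p, 0), 1)
}

# cache of combn index matrices, keyed by "nx/ny" (the enumeration is hit
# tens of thousands of times in calibration experiments)
.combn_cache <- new.env(parent = emptyenv())

combn_sets <- function(nx, ny) {
  key <- paste0(nx, "/", ny)
  if (is.null(.combn_cache[[key]]))
    .combn_cache[[key]] <- utils::combn(nx + ny, nx)
  .combn_cache[[key]]
}

# Exact one-sided rank-sum p-value by enumeration of all group
# reassignments, with midranks for ties. P(W >= W_obs) where W is the rank
# sum of the first sample under random relabelling of the pooled values.
# With 5-vs-5 groups of tied fractions the null is deeply discrete; the
# normal approximation is ambiguous there, enumeration is not.
exact_ranksum_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)])
  sets <- combn_sets(nx, ny)
  w_all <- colSums(matrix(r[sets], nrow = nx))
  mean(w_all >= w_obs - 1e-9)
}

# One-sided (x stochastically greater) rank-sum p-value; exact enumeration
# when both sides are small, tie-corrected normal approximation otherwise.
ranksum_greater_p <- function(x, y, exact_max = 8L) {
  if (length(x) <= exact_max && length(y) <= exact_max)
    exact_ranksum_p(x, y)
  else
    suppressWarnings(stats::wilcox.test(x, y, alternative = "greater",
                                        exact = FALSE, correct = TRUE)$p.value)
}

#' Shuffled-partition rank-sum criterion
#'
#' The second calling criterion, which guards against calls driven by a
#' single injection round: all embryos of the candidate construct are
#' shuffled and partitioned into `n_partitions` near-equal groups, the
#' expressing fraction of each group is computed for the given anatomy, the
#' same is done for the control embryos, and the candidate group fractions
#' are compared to the control group fractions with a one-sided Wilcoxon
#' rank-sum test (candidate greater). The procedure is repeated `n_runs`
#' times and the arithmetic mean of the p-values is returned.
#'
#' Group sizes differ by at most one embryo. With the default 5-vs-5 groups
#' the rank-sum null is enumerated exactly (tie-aware); larger group counts
#' fall back to the tie-corrected normal approximation.
#'
#' @param cce,control [expression_matrix()] objects.
#' @param anatomy anatomy name or code.
#' @param n_partitions groups per side (default 5).
#' @param n_runs independent shuffles averaged (default 3).
#' @param seed integer seed; per-run substreams are derived from it.
#' @return mean one-sided p-value across runs.
#' @export
partition_ranksum <- function(cce, control, anatomy, n_partitions = 5L,
                              n_runs = 3L, seed = 1L) {
  a <- resolve_anatomy(cce, anatomy)
  if (n_embryos(cce) < n_partitions || n_embryos(control) < n_partitions)
    stopf("need at least %d embryos per side for %d partitions",
          n_partitions, n_partitions)
  x_bits <- cce$data[, a]
  y_bits <- control$data[, a]
  ps <- vapply(seq_len(n_runs), function(run) {
    with_seed(derive_seed(seed, cce$construct_id, a, run), {
      ranksum_greater_p(partition_fractions(x_bits, n_partitions),
                        partition_fractions(y_bits, n_partitions))
    })
  }, 0.0)
  mean(ps)
}

# Shuffle a 0/1 vector and return the expressing fraction of each of g
# near-equal groups (sizes differ by at most 1; the first n %% g groups get
# the extra embryo).
partition_fractions <- function(bits, g) {
  n <- length(bits)
  bits <- bits[sample.int(n)]
  sizes <- rep(n %/% g, g) + c(rep(1L, n %% g), rep(0L, g - n %% g))
  grp <- rep(seq_len(g), times = sizes)
  as.numeric(tapply(bits, grp, mean))
}

resolve_anatomy <- function(m, anatomy) {
  if (is.numeric(anatomy)) {
    if (anatomy < 1 || anatomy > ncol(m$data)) stopf("anatomy code out of range")
    return(as.integer(anatomy))
  }
  i <- match(anatomy, m$vocabulary$name)
  if (is.na(i)) stopf("anatomy '%s' not in vocabulary", anatomy)
  i
}

#' Dual-rule significance decision
#'
#' An anatomy is called significant for a construct when BOTH the
#' proportions-test p-value and the mean partition rank-sum p-value are at
#' or below `alpha`.
#'
#' @param p_prop,p_ranksum numeric vectors of per-anatomy p-values (same
#'   anatomies, same order).
#' @param alpha significance level (default 0.05).
#' @return logical vector of significance decisions.
#' @export
call_anatomies <- function(p_prop, p_ranksum, alpha = 0.05) {
  if (length(p_prop) != length(p_ranksum))
    stopf("p-value vectors cover different anatomies")
  !is.na(p_prop) & !is.na(p_ranksum) & p_prop <= alpha & p_ranksum <= alpha
}

#' Fold ratio of expressing fractions
#'
#' Ratio of the candidate expressing fraction to the control fraction,
#' reported for significant anatomies; undefined (NA) where the control
#' fraction is zero.
#'
#' @param p_cce,p_control expressing fractions.
#' @param digits decimals for display rounding (default 1, as reported).
#' @return numeric ratio (rounded), NA where the control fraction is 0.
#' @export
fold_ratio <- function(p_cce, p_control, digits = 1) {
  ifelse(p_control > 0, round(p_cce / p_control, digits), NA_real_)
}

#' Classify construct-level activity
#'
#' Whole-construct classification from the per-anatomy decisions:
#' `none` when fewer than `none_threshold` of embryos express anywhere,
#' `significant` when at least one anatomy passes the dual rule, `weak`
#' otherwise. Significant constructs are `specific` when they are active in
#' `specific_max` (default 4) or fewer anatomies, else `nonspecific`.
#'
#' @param n_significant number of significant anatomies.
#' @param whole_embryo_fraction fraction of embryos with >= 1 active anatomy.
#' @param none_threshold below this whole-embryo fraction the construct is
#'   called inactive (default 0.05).
#' @param specific_max maximum significant anatomies for a specific call.
#' @return list with `activity_class` and `specificity`.
#' @export
classify_activity <- function(n_significant, whole_embryo_fraction,
                              none_threshold = 0.05, specific_max = 4L) {
  activity <- if (whole_embryo_fraction < none_threshold) "none"
  else if (n_significant >= 1) "significant"
  else "weak"
  specificity <- if (activity != "significant") "not-applicable"
  else if (n_significant <= specific_max) "specific" else "nonspecific"
  list(activity_class = activity, specificity = specificity)
}

#' Reconstruct integer counts from printed proportions
#'
#' Published tables report expressing fractions to four decimals rather than
#' raw counts. For each proportion this finds the integer count k minimising
#' |k/n - p| and flags cells where even the best k fails the requested
#' tolerance (i.e. the printed value is not an exact k/n rounding).
#'
#' @param p vector of printed proportions.
#' @param n total embryos (scalar or vector).
#' @param tol reconstruction tolerance on |k/n - p| (default 5e-5, exact
#'   four-decimal agreement).
#' @return data frame with columns `p`, `n`, `k`, `error`, `ok`.
#' @export
reconstruct_counts <- function(p, n, tol = 5e-5) {
  n <- rep_len(n, length(p))
  k <- pmin(pmax(round(p * n), 0), n)
  err <- abs(k / n - p)
  data.frame(p = p, n = n, k = as.integer(k), error = err, ok = err < tol)
}
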