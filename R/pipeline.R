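#' Run the full calling study over a set of constructs
#'
#' Orchestrates the per-construct pipeline: dual-rule enhancer calling
#' against the shared control ([enhancer_call()]), construct
#' classification, and the all-pairs concurrency screen
#' ([concurrency_pairs()]). Per-construct substream seeds are derived
#' deterministically from the single study seed, so reruns are
#' byte-identical.
#'
#' @param cce_matrices named list of [expression_matrix()] objects, one per
#'   candidate construct.
#' @param control the control [expression_matrix()].
#' @param alpha,n_partitions,n_runs,none_threshold,specific_max call
#'   parameters, see [enhancer_call()].
#' @param concurrency_alpha flagging level of the concurrency screen.
#' @param seed study seed.
#' @return an object of class `study_report`: `calls` (list of
#'   `enhancer_call`), `concurrency` (list of pair tables), and `summary`
#'   (per-construct classification data frame plus global counts).
#' @export
run_study <- function(cce_matrices, control, alpha = 0.05,
                      n_partitions = 5L, n_runs = 3L,
                      none_threshold = 0.05, specific_max = 4L,
                      concurrency_alpha = 0.05, seed = 1L) {
  if (length(cce_matrices) < 1) stopf("no candidate constructs supplied")
  if (!inherits(control, "expression_matrix"))
    stopf("calling stage: control matrix missing or invalid")
  calls <- lapply(cce_matrices, function(m)
    enhancer_call(m, control, alpha = alpha, n_partitions = n_partitions,
                  n_runs = n_runs, none_threshold = none_threshold,
                  specific_max = specific_max,
                  seed = derive_seed(seed, m$construct_id)))
  conc <- lapply(cce_matrices, concurrency_pairs,
                 alpha = concurrency_alpha)
  per <- data.frame(
    construct = vapply(calls, function(x) x$construct_id, ""),
    n_embryos = vapply(cce_matrices, n_embryos, 0L),
    n_significant = vapply(calls, function(x)
      length(x$significant_anatomies), 0L),
    whole_embryo_fraction = vapply(calls, function(x)
      x$whole_embryo_fraction, 0.0),
    activity_class = vapply(calls, function(x) x$activity_class, ""),
    specificity = vapply(calls, function(x) x$specificity, ""),
    stringsAsFactors = FALSE, row.names = NULL)
  counts <- c(total = nrow(per),
              significant = sum(per$activity_class == "significant"),
              weak = sum(per$activity_class == "weak"),
              none = sum(per$activity_class == "none"),
              specific = sum(per$specificity == "specific"),
              nonspecific = sum(per$specificity == "nonspecific"))
  structure(list(calls = calls, concurrency = conc,
                 summary = list(per_construct = per, counts = counts),
                 parameters = list(alpha = alpha,
                                   n_partitions = n_partitions,
                                   n_runs = n_runs,
                                   none_threshold = none_threshold,
                                   specific_max = specific_max,
                                   seed = seed)),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  ct <- x$summary$counts
  cat(sprintf("Study report: %d constructs (seed %d)\n", ct["total"],
              x$parameters$seed))
  cat(sprintf("  significant %d (specific %d, nonspecific %d), weak %d, none %d\n",
              ct["significant"], ct["specific"], ct["nonspecific"],
              ct["weak"], ct["none"]))
  invisible(x)
}

#' Compare two construct cohorts
#'
#' Cohort-level comparison of activity and specificity rates (e.g.
#' conserved coding vs conserved noncoding elements): fractions with
#' binomial s.e.m. and two-sided two-proportion p-values. Accepts either
#' two `study_report` objects or explicit count lists
#' `list(active = c(k, n), specific = c(k, n))`.
#'
#' @param a,b study reports or count lists.
#' @return data frame with one row per comparison (`activity`,
#'   `specificity`): cohort fractions, s.e.m.s and the p-value.
#' @export
compare_cohorts <- function(a, b) {
  as_counts <- function(x) {
    if (inherits(x, "study_report")) {
      ct <- x$summary$counts
      if (ct["total"] < 1) stopf("empty cohort")
      list(active = c(ct[["significant"]], ct[["total"]]),
           specific = c(ct[["specific"]], ct[["significant"]]))
    } else x
  }
  ca <- as_counts(a); cb <- as_counts(b)
  row <- function(label, ka, na, kb, nb) {
    data.frame(comparison = label,
               k_a = ka, n_a = na, fraction_a = ka / na,
               sem_a = binomial_sem(ka, na),
               k_b = kb, n_b = nb, fraction_b = kb / nb,
               sem_b = binomial_sem(kb, nb),
               p_value = two_proportion_compare(ka, na, kb, nb),
               stringsAsFactors = FALSE)
  }
  rbind(row("activity", ca$active[1], ca$active[2],
            cb$active[1], cb$active[2]),
        row("specificity", ca$specific[1], ca$specific[2],
            cb$specific[1], cb$specific[2]))
}
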