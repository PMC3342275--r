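#' Published example calling statistics
#'
#' The worked-example statistics shipped with the package: per-anatomy
#' expressing proportions, the two calling p-values, and the reported fold
#' ratio for significant anatomies, for a minimal-promoter control (161
#' embryos) and four candidate coding-exon constructs (CCE-rab11fip4a,
#' CCE-abca1a, CCE-odz3, CCE-rfx2). These are the printed summary
#' statistics of the assay, not raw embryo data; [reconstruct_counts()]
#' recovers integer embryo counts from the proportions. Control rows carry
#' `NA` p-values (the control is the reference, not a tested construct);
#' `fold` is `NA` for anatomies not called significant.
#'
#' @return data frame with columns `construct`, `n_embryos`, `anatomy`,
#'   `proportion`, `p_prop`, `p_ranksum`, `fold`.
#' @examples
#' stats <- cce_example_stats()
#' subset(stats, !is.na(fold))   # the eight significant cells
#' @export
cce_example_stats <- function() {
  path <- system.file("extdata", "cce_example_stats.tsv",
                      package = "exonhancer", mustWork = TRUE)
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Simulation spec preset mirroring an example construct
#'
#' Builds an [embryo_sim_spec()] whose anatomy probabilities and embryo
#' count equal the published proportions of one example construct, for
#' calibration and power experiments at realistic effect sizes.
#'
#' @param construct one of the constructs in [cce_example_stats()].
#' @param seed integer seed for the spec.
#' @return an [embryo_sim_spec()].
#' @export
example_sim_spec <- function(construct = "control", seed = 1L) {
  stats <- cce_example_stats()
  rows <- stats[stats$construct == construct, ]
  if (nrow(rows) == 0)
    stopf("unknown construct '%s'; see cce_example_stats()", construct)
  embryo_sim_spec(n_embryos = rows$n_embryos[1],
                  anatomy_probs = rows$proportion, seed = seed)
}
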