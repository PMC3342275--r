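#' Null calibration of the dual calling rule
#'
#' Simulates candidate and control matrices that are iid draws from the
#' same per-anatomy Bernoulli law (the global null) and measures the
#' per-anatomy false-call rate of the dual rule at level `alpha`. The
#' conjunction of two level-alpha criteria cannot exceed alpha for the less
#' powerful criterion, so the observed rate should sit at or below `alpha`
#' up to Monte-Carlo error.
#'
#' @param control_probs per-anatomy activity probabilities under the null.
#' @param n_cce,n_control embryos per simulated candidate / control.
#' @param n_replicates simulation replicates.
#' @param alpha dual-rule level.
#' @param n_partitions,n_runs rank-sum parameters.
#' @param seed integer seed; replicate substreams derive from it.
#' @return list with `rate` (pooled false-call rate over replicates x
#'   anatomies), `n_tests`, and `mc_se` (binomial Monte-Carlo standard
#'   error of a rate at `alpha`).
#' @export
dual_rule_null_rate <- function(control_probs, n_cce = 120L,
                                n_control = 161L, n_replicates = 1000L,
                                alpha = 0.05, n_partitions = 5L,
                                n_runs = 3L, seed = 1L) {
  vocab <- anatomy_vocabulary(paste0("a", seq_along(control_probs)))
  calls <- 0L
  for (r in seq_len(n_replicates)) {
    cce <- simulate_embryos(embryo_sim_spec(n_cce, control_probs,
                                            seed = derive_seed(seed, "cce", r)),
                            vocab = vocab, construct_id = "null-cce")
    ctrl <- simulate_embryos(embryo_sim_spec(n_control, control_probs,
                                             seed = derive_seed(seed, "ctl", r)),
                             vocab = vocab, construct_id = "control")
    pc <- expression_proportions(cce); p0 <- expression_proportions(ctrl)
    for (a in seq_along(control_probs)) {
      pp <- proportions_test(pc$k[a], pc$n[a], p0$k[a], p0$n[a])
      if (pp > alpha) next  # rank-sum cannot rescue a failed first criterion
      pr <- partition_ranksum(cce, ctrl, a, n_partitions = n_partitions,
                              n_runs = n_runs,
                              seed = derive_seed(seed, "rs", r, a))
      if (call_anatomies(pp, pr, alpha = alpha)) calls <- calls + 1L
    }
  }
  n_tests <- n_replicates * length(control_probs)
  list(rate = calls / n_tests, n_tests = n_tests,
       mc_se = sqrt(alpha * (1 - alpha) / n_tests))
}

#' Recovery rate of a planted per-anatomy effect
#'
#' Simulates candidate constructs whose activity matches the control law
#' except for one planted anatomy with elevated probability, and measures
#' how often the dual rule recovers the planted anatomy across seeds.
#'
#' @param control_probs per-anatomy control probabilities.
#' @param effect_prob planted activity probability.
#' @param anatomy index of the planted anatomy.
#' @param n_cce,n_control embryos per side.
#' @param n_seeds independent simulated constructs.
#' @param alpha,n_partitions,n_runs calling parameters.
#' @param seed integer base seed.
#' @return recovery fraction over seeds.
#' @export
dual_rule_recovery_rate <- function(control_probs, effect_prob, anatomy,
                                    n_cce = 53L, n_control = 161L,
                                    n_seeds = 200L, alpha = 0.05,
                                    n_partitions = 5L, n_runs = 3L,
                                    seed = 1L) {
  vocab <- anatomy_vocabulary(paste0("a", seq_along(control_probs)))
  probs <- control_probs
  probs[anatomy] <- effect_prob
  hits <- 0L
  for (r in seq_len(n_seeds)) {
    cce <- simulate_embryos(embryo_sim_spec(n_cce, probs,
                                            seed = derive_seed(seed, "eff", r)),
                            vocab = vocab, construct_id = "planted")
    ctrl <- simulate_embryos(embryo_sim_spec(n_control, control_probs,
                                             seed = derive_seed(seed, "ctl", r)),
                             vocab = vocab, construct_id = "control")
    pc <- expression_proportions(cce); p0 <- expression_proportions(ctrl)
    pp <- proportions_test(pc$k[anatomy], pc$n[anatomy],
                           p0$k[anatomy], p0$n[anatomy])
    pr <- partition_ranksum(cce, ctrl, anatomy,
                            n_partitions = n_partitions, n_runs = n_runs,
                            seed = derive_seed(seed, "rs", r))
    if (call_anatomies(pp, pr, alpha = alpha)) hits <- hits + 1L
  }
  hits / n_seeds
}

#' Flag rate of the concurrency statistic under its stated null
#'
#' Simulates embryo matrices in which each of the four joint activity
#' patterns of an anatomy pair has probability exactly 1/4 (independent
#' Bernoulli(0.5) margins) and measures the one-sided flag rate at
#' `alpha`. The binomial discreteness of N11 keeps the rate near but not
#' exactly at `alpha`.
#'
#' @param n_embryos embryos per replicate.
#' @param n_replicates replicates.
#' @param alpha flag level.
#' @param seed integer seed.
#' @return observed flag rate.
#' @export
concurrency_null_rate <- function(n_embryos = 400L, n_replicates = 2000L,
                                  alpha = 0.05, seed = 1L) {
  vocab <- anatomy_vocabulary(c("A", "B"))
  flags <- vapply(seq_len(n_replicates), function(r) {
    m <- simulate_embryos(embryo_sim_spec(n_embryos, c(0.5, 0.5),
                                          seed = derive_seed(seed, "cc", r)),
                          vocab = vocab)
    concurrency_z(pair_counts(m, 1, 2))$p < alpha
  }, FALSE)
  mean(flags)
}
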