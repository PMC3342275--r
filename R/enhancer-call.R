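#' Call per-anatomy enhancer activity against a control
#'
#' The central fitting function of the package. For one candidate construct
#' it computes, per anatomy, the expressing proportion, the one-sided
#' continuity-corrected two-proportion p-value against the minimal-promoter
#' control ([proportions_test()]), and the mean shuffled-partition rank-sum
#' p-value ([partition_ranksum()]); applies the dual rule (both p-values at
#' or below `alpha`); attaches fold ratios for significant anatomies; and
#' classifies the construct as significant/weak/none and
#' specific/nonspecific ([classify_activity()]).
#'
#' @param cce [expression_matrix()] for the candidate construct (all
#'   injection batches merged).
#' @param control [expression_matrix()] for the minimal-promoter control.
#' @param alpha dual-rule significance level (default 0.05).
#' @param n_partitions,n_runs partition rank-sum parameters (defaults 5, 3).
#' @param none_threshold whole-embryo expressing fraction below which the
#'   construct is called inactive (default 0.05).
#' @param specific_max maximum significant anatomies for a "specific" call
#'   (default 4).
#' @param seed integer seed driving the shuffled partitions.
#' @return an object of class `enhancer_call` with components `table` (per
#'   anatomy: `anatomy`, `k_cce`, `n_cce`, `p_cce`, `k_ctrl`, `n_ctrl`,
#'   `p_ctrl`, `fold`, `p_prop`, `p_ranksum`, `significant`),
#'   `construct_id`, `significant_anatomies`, `whole_embryo_fraction`,
#'   `activity_class`, `specificity`, and the call parameters.
#' @examples
#' spec <- embryo_sim_spec(n_embryos = 120,
#'                         anatomy_probs = c(0.6, rep(0.1, 9)), seed = 7)
#' cce <- simulate_embryos(spec, construct_id = "CCE-demo")
#' ctrl <- simulate_embryos(embryo_sim_spec(n_embryos = 160,
#'                          anatomy_probs = rep(0.1, 10), seed = 8),
#'                          construct_id = "control")
#' fit <- enhancer_call(cce, ctrl, seed = 1)
#' fit
#' @seealso [summary.enhancer_call()], [coef.enhancer_call()],
#'   [concurrency_pairs()], [run_study()]
#' @export
enhancer_call <- function(cce, control, alpha = 0.05, n_partitions = 5L,
                          n_runs = 3L, none_threshold = 0.05,
                          specific_max = 4L, seed = 1L) {
  if (!identical(cce$vocabulary$name, control$vocabulary$name))
    stopf("candidate and control use different vocabularies")
  if (n_embryos(cce) < 1 || n_embryos(control) < 1)
    stopf("empty expression matrix")
  prop_c <- expression_proportions(cce)
  prop_0 <- expression_proportions(control)
  anat <- prop_c$anatomy
  p_prop <- vapply(seq_along(anat), function(i)
    proportions_test(prop_c$k[i], prop_c$n[i], prop_0$k[i], prop_0$n[i]), 0.0)
  p_rs <- vapply(anat, function(a)
    partition_ranksum(cce, control, a, n_partitions = n_partitions,
                      n_runs = n_runs, seed = seed), 0.0)
  sig <- call_anatomies(p_prop, p_rs, alpha = alpha)
  tab <- data.frame(
    anatomy = anat,
    k_cce = prop_c$k, n_cce = prop_c$n, p_cce = prop_c$p_hat,
    k_ctrl = prop_0$k, n_ctrl = prop_0$n, p_ctrl = prop_0$p_hat,
    fold = ifelse(sig, fold_ratio(prop_c$p_hat, prop_0$p_hat), NA_real_),
    p_prop = p_prop, p_ranksum = unname(p_rs), significant = sig,
    stringsAsFactors = FALSE)
  wef <- mean(rowSums(cce$data) >= 1)
  cls <- classify_activity(sum(sig), wef, none_threshold = none_threshold,
                           specific_max = specific_max)
  structure(list(construct_id = cce$construct_id, table = tab,
                 significant_anatomies = anat[sig],
                 whole_embryo_fraction = wef,
                 activity_class = cls$activity_class,
                 specificity = cls$specificity,
                 alpha = alpha, n_partitions = n_partitions,
                 n_runs = n_runs, none_threshold = none_threshold,
                 specific_max = specific_max, seed = seed),
            class = "enhancer_call")
}

#' @export
print.enhancer_call <- function(x, digits = 4, ...) {
  cat(sprintf("Enhancer call for '%s' (alpha = %g, %d-vs-%d partition rank-sum, %d runs)\n",
              x$construct_id, x$alpha, x$n_partitions, x$n_partitions,
              x$n_runs))
  cat(sprintf("  activity: %s (%s); %.1f%% of embryos express somewhere\n",
              x$activity_class, x$specificity,
              100 * x$whole_embryo_fraction))
  if (length(x$significant_anatomies))
    cat("  significant anatomies:",
        paste(x$significant_anatomies, collapse = ", "), "\n")
  else cat("  no significant anatomies\n")
  invisible(x)
}

#' Summarise an enhancer call
#'
#' @param object an [enhancer_call()] fit.
#' @param ... unused.
#' @export
summary.enhancer_call <- function(object, ...) {
  structure(object, class = c("summary.enhancer_call", "enhancer_call"))
}

#' @export
print.summary.enhancer_call <- function(x, digits = 4, ...) {
  NextMethod()
  tab <- x$table
  tab$p_cce <- round(tab$p_cce, digits)
  tab$p_ctrl <- round(tab$p_ctrl, digits)
  tab$p_prop <- signif(tab$p_prop, 3)
  tab$p_ranksum <- signif(tab$p_ranksum, 3)
  print(tab[, c("anatomy", "p_cce", "p_ctrl", "fold", "p_prop",
                "p_ranksum", "significant")], row.names = FALSE)
  invisible(x)
}

#' Per-anatomy estimates of an enhancer call
#'
#' Returns the per-anatomy coefficient matrix: candidate and control
#' expressing fractions, fold ratio, and the two p-values.
#'
#' @param object an [enhancer_call()] fit.
#' @param ... unused.
#' @export
coef.enhancer_call <- function(object, ...) {
  m <- as.matrix(object$table[, c("p_cce", "p_ctrl", "fold", "p_prop",
                                  "p_ranksum")])
  rownames(m) <- object$table$anatomy
  m
}

#' Barplot of candidate vs control expressing fractions
#'
#' @param x an [enhancer_call()] fit.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.enhancer_call <- function(x, ...) {
  tab <- x$table
  h <- rbind(candidate = tab$p_cce, control = tab$p_ctrl)
  colnames(h) <- abbreviate(tab$anatomy, 8)
  bp <- graphics::barplot(h, beside = TRUE, las = 2,
                          ylab = "expressing fraction",
                          main = x$construct_id,
                          legend.text = TRUE, ...)
  if (any(tab$significant))
    graphics::mtext("*", side = 1, at = colMeans(bp)[tab$significant],
                    line = -1.2, cex = 1.4)
  invisible(bp)
}
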