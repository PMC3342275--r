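#' Specification for simulated embryo scoring data
#'
#' Describes the generative law for a synthetic embryo-by-anatomy matrix:
#' independent per-anatomy Bernoulli activity, optional per-batch
#' multiplicative odds shifts (injection-round variability), and optional
#' co-active anatomy pairs driven by a shared latent indicator that is OR'd
#' into both anatomies (so the joint law stays closed-form and the
#' concurrency statistic can be checked analytically).
#'
#' @param n_embryos number of surviving embryos.
#' @param anatomy_probs per-anatomy baseline activity probabilities.
#' @param batch_sizes integer vector of embryos per injection round
#'   (defaults to one batch of `n_embryos`); must sum to `n_embryos`.
#' @param batch_odds per-batch multiplicative odds shifts (default all 1).
#' @param coactive_pairs list of `list(a =, b =, joint_boost =)` entries:
#'   with probability `joint_boost` a latent co-activation turns both
#'   anatomies on in an embryo.
#' @param seed integer seed.
#' @return a classed list used by [simulate_embryos()].
#' @export
embryo_sim_spec <- function(n_embryos, anatomy_probs,
                            batch_sizes = NULL, batch_odds = NULL,
                            coactive_pairs = list(), seed = 1L) {
  if (any(anatomy_probs < 0 | anatomy_probs > 1))
    stopf("anatomy probabilities must lie in [0, 1]")
  if (is.null(batch_sizes)) batch_sizes <- n_embryos
  if (sum(batch_sizes) != n_embryos)
    stopf("batch sizes must sum to n_embryos")
  if (is.null(batch_odds)) batch_odds <- rep(1, length(batch_sizes))
  if (length(batch_odds) != length(batch_sizes))
    stopf("one odds shift per batch required")
  for (cp in coactive_pairs)
    if (cp$joint_boost < 0 || cp$joint_boost > 1)
      stopf("joint_boost must lie in [0, 1]")
  structure(list(n_embryos = as.integer(n_embryos),
                 anatomy_probs = anatomy_probs,
                 batch_sizes = as.integer(batch_sizes),
                 batch_odds = batch_odds,
                 coactive_pairs = coactive_pairs, seed = as.integer(seed)),
            class = "embryo_sim_spec")
}

#' Simulate a scored embryo matrix with known ground truth
#'
#' @param spec an [embryo_sim_spec()].
#' @param vocab vocabulary; `anatomy_probs` must match its size.
#' @param construct_id construct label.
#' @return an [expression_matrix()]; attribute `truth` holds the spec, the
#'   per-batch activity probabilities actually used, and the marginal
#'   per-anatomy probabilities after co-activation.
#' @export
simulate_embryos <- function(spec, vocab = default_vocabulary(),
                             construct_id = "synthetic") {
  if (length(spec$anatomy_probs) != nrow(vocab))
    stopf("spec has %d anatomy probabilities but vocabulary has %d",
          length(spec$anatomy_probs), nrow(vocab))
  nb <- length(spec$batch_sizes)
  # odds-scale batch shifts keep probabilities in range
  shift <- function(p, s) ifelse(p %in% c(0, 1), p,
                                 p * s / (1 - p + p * s))
  batch_probs <- lapply(spec$batch_odds, function(s)
    shift(spec$anatomy_probs, s))
  m <- with_seed(spec$seed, {
    rows <- lapply(seq_len(nb), function(j) {
      nj <- spec$batch_sizes[j]
      mj <- matrix(stats::rbinom(nj * nrow(vocab), 1,
                                 rep(batch_probs[[j]], each = nj)),
                   nrow = nj)
      for (cp in spec$coactive_pairs) {
        lat <- stats::rbinom(nj, 1, cp$joint_boost)
        mj[, cp$a] <- pmax(mj[, cp$a], lat)
        mj[, cp$b] <- pmax(mj[, cp$b], lat)
      }
      mj
    })
    do.call(rbind, rows)
  })
  out <- expression_matrix(m, vocab = vocab, construct_id = construct_id,
                           batch_id = rep(paste0("batch",
                                                 seq_len(nb)),
                                          times = spec$batch_sizes))
  marg <- Reduce(`+`, Map(function(p, n) p * n, batch_probs,
                          spec$batch_sizes)) / spec$n_embryos
  for (cp in spec$coactive_pairs) {
    marg[cp$a] <- cp$joint_boost + (1 - cp$joint_boost) * marg[cp$a]
    marg[cp$b] <- cp$joint_boost + (1 - cp$joint_boost) * marg[cp$b]
  }
  attr(out, "truth") <- list(spec = spec, batch_probs = batch_probs,
                             marginal_probs = marg)
  out
}

#' Render a matrix back into a dictation transcript
#'
#' Inverse of [parse_transcript()]: emits one `"new"` token per embryo
#' followed by the numeric codes of its active anatomies. With
#' `noise_rate > 0`, anatomy tokens are replaced by a random synonym and
#' spurious unrecognisable tokens are injected, each independently at
#' `noise_rate`, to exercise the parser's error policies; the injected
#' noise is logged in the `noise_log` attribute.
#'
#' @param m an [expression_matrix()].
#' @param noise_rate per-token noise probability (default 0).
#' @param seed seed for the noise stream.
#' @return a single transcript string.
#' @export
render_transcript <- function(m, noise_rate = 0, seed = 1L) {
  vocab <- m$vocabulary
  log <- character()
  toks <- with_seed(if (noise_rate > 0) seed else NULL, {
    out <- character()
    for (i in seq_len(n_embryos(m))) {
      out <- c(out, "new")
      for (code in which(m$data[i, ] == 1L)) {
        tok <- as.character(code)
        if (noise_rate > 0 && stats::runif(1) < noise_rate &&
            length(vocab$synonyms[[code]]) > 0) {
          tok <- sample(vocab$synonyms[[code]], 1)
          log <- c(log, sprintf("embryo %d: synonym '%s' for code %d",
                                i, tok, code))
        }
        out <- c(out, tok)
        if (noise_rate > 0 && stats::runif(1) < noise_rate) {
          out <- c(out, "garbled")
          log <- c(log, sprintf("embryo %d: spurious token", i))
        }
      }
    }
    out
  })
  txt <- paste(toks, collapse = " ")
  attr(txt, "noise_log") <- log
  txt
}

#' Simulate an annotation table, ontology and anatomy map
#'
#' Builds a two-level toy ontology (one seed term per scored anatomy, each
#' with `n_children` child terms), the anatomy map onto the seed terms, and
#' a gene annotation table in which every gene independently receives, for
#' each anatomy, an in-window expression record (drawn from the anatomy's
#' expanded term set) with probability `match_prob` -- so whether a random
#' gene matches a given call anatomy is iid Bernoulli(`match_prob`) and the
#' permutation null has a binomial closed form. Additional decoy records
#' with out-of-window stages exercise the stage filter.
#'
#' @param n_genes number of genes.
#' @param match_prob per-anatomy in-window record probability.
#' @param vocab anatomy vocabulary.
#' @param n_children children per seed term (default 2).
#' @param n_stages length of the synthetic stage order (default 10).
#' @param decoy_rate probability of an extra out-of-window record per gene.
#' @param seed integer seed.
#' @return list with `ontology`, `map`, `table`, `stage_order`, `window`
#'   (the in-window stage window) and `truth` (gene-by-anatomy logical
#'   matrix of planted in-window matches).
#' @export
simulate_annotations <- function(n_genes, match_prob,
                                 vocab = default_vocabulary(),
                                 n_children = 2L, n_stages = 10L,
                                 decoy_rate = 0.2, seed = 1L) {
  anat <- vocab$name
  stage_order <- paste0("stage", seq_len(n_stages))
  # window covers the middle stages; decoys live strictly after it
  win_lo <- 2L; win_hi <- max(3L, n_stages - 3L)
  window <- stage_window(stage_order[win_lo], stage_order[win_hi],
                         stage_order)
  seeds <- paste0("TERM:", sprintf("%04d", seq_along(anat)))
  kids <- if (n_children > 0) data.frame(
    term_id = paste0("TERM:c", rep(seq_along(anat), each = n_children),
                     "_", rep(seq_len(n_children), length(anat))),
    name = paste0(rep(tolower(anat), each = n_children), " part ",
                  rep(seq_len(n_children), length(anat))),
    parent_id = rep(seeds, each = n_children), stringsAsFactors = FALSE)
  else data.frame(term_id = character(), name = character(),
                  parent_id = character(), stringsAsFactors = FALSE)
  ont <- ontology(rbind(
    data.frame(term_id = seeds, name = tolower(anat),
               parent_id = NA_character_, stringsAsFactors = FALSE),
    kids,
    data.frame(term_id = "TERM:whole_organism", name = "whole organism",
               parent_id = NA_character_, stringsAsFactors = FALSE)))
  map <- anatomy_map(data.frame(anatomy = anat, term_id = seeds,
                                stringsAsFactors = FALSE))
  genes <- paste0("gene", sprintf("%04d", seq_len(n_genes)))
  truth <- matrix(FALSE, n_genes, length(anat),
                  dimnames = list(genes, anat))
  recs <- with_seed(seed, {
    out <- list()
    for (gi in seq_len(n_genes)) {
      for (ai in seq_along(anat)) {
        if (stats::runif(1) < match_prob) {
          truth[gi, ai] <- TRUE
          terms <- expand_terms(anat[ai], map, ont)
          s <- sample(win_lo:win_hi, 1)
          out[[length(out) + 1]] <- data.frame(
            gene_id = genes[gi], term_id = sample(terms, 1),
            start_stage = stage_order[s],
            end_stage = stage_order[min(s + 1L, n_stages)],
            assay = "mRNA in situ hybridization",
            probe_quality = sample(3:5, 1), stringsAsFactors = FALSE)
        }
      }
      if (stats::runif(1) < decoy_rate && win_hi < n_stages - 1L) {
        out[[length(out) + 1]] <- data.frame(
          gene_id = genes[gi],
          term_id = sample(ont$term_id, 1),
          start_stage = stage_order[win_hi + 1L],
          end_stage = stage_order[n_stages],
          assay = "mRNA in situ hybridization",
          probe_quality = sample(1:5, 1), stringsAsFactors = FALSE)
      }
      # every gene in the emulated expression file carries at least one
      # annotation, so the random-gene sampling universe is the whole
      # gene set, not just genes with anatomy-matching records
      out[[length(out) + 1]] <- data.frame(
        gene_id = genes[gi], term_id = "TERM:whole_organism",
        start_stage = stage_order[win_lo], end_stage = stage_order[win_hi],
        assay = "mRNA in situ hybridization",
        probe_quality = 3L, stringsAsFactors = FALSE)
    }
    out
  })
  tab <- if (length(recs)) do.call(rbind, recs)
  else data.frame(gene_id = character(), term_id = character(),
                  start_stage = character(), end_stage = character(),
                  assay = character(), probe_quality = integer(),
                  stringsAsFactors = FALSE)
  # every gene appears in the table even without in-window records, so
  # "no data" flags are about genes absent from this gene universe
  list(ontology = ont, map = map,
       table = annotation_table(tab, stage_order),
       stage_order = stage_order, window = window,
       genes = genes, truth = truth)
}

#' Simulate a pairwise coding alignment with known site-class identities
#'
#' Generates in-frame codon pairs: roughly half the codons come from
#' fourfold-degenerate families, the rest from twofold families. Third
#' positions of fourfold codons are conserved with probability
#' `id_fourfold`; twofold third positions with probability `id_twofold`
#' (swapping to the synonymous partner); first/second positions mutate with
#' probability `1 - id_nonsyn` per codon. Whole codons of one sequence are
#' replaced by gaps at `gap_rate`.
#'
#' @param n_codons codons in the ungapped frame.
#' @param id_fourfold,id_twofold,id_nonsyn per-class identity targets.
#' @param fourfold_frac fraction of codons drawn from fourfold families.
#' @param gap_rate per-codon whole-codon gap probability.
#' @param seed integer seed.
#' @return an [aligned_cds_pair()]; attribute `truth` records the spec and
#'   the realised per-class conservation.
#' @export
simulate_cds_pair <- function(n_codons, id_fourfold = 0.5,
                              id_twofold = 0.8, id_nonsyn = 0.95,
                              fourfold_frac = 0.5, gap_rate = 0,
                              seed = 1L) {
  twofold <- list(c("TTA", "TTG"), c("AAA", "AAG"), c("GAA", "GAG"),
                  c("CAA", "CAG"), c("GAT", "GAC"), c("AAT", "AAC"))
  nts <- c("A", "C", "G", "T")
  with_seed(seed, {
    is4 <- stats::runif(n_codons) < fourfold_frac
    cod_a <- character(n_codons); cod_b <- character(n_codons)
    third_cons <- logical(n_codons)
    prefix_intact <- rep(TRUE, n_codons)
    for (i in seq_len(n_codons)) {
      if (is4[i]) {
        pre <- sample(FOURFOLD_PREFIXES, 1)
        t3 <- sample(nts, 1)
        cod_a[i] <- paste0(pre, t3)
        third_cons[i] <- stats::runif(1) < id_fourfold
        t3b <- if (third_cons[i]) t3 else sample(setdiff(nts, t3), 1)
        cod_b[i] <- paste0(pre, t3b)
      } else {
        fam <- twofold[[sample.int(length(twofold), 1)]]
        a <- sample(fam, 1)
        cod_a[i] <- a
        third_cons[i] <- stats::runif(1) < id_twofold
        cod_b[i] <- if (third_cons[i]) a else setdiff(fam, a)
      }
      if (stats::runif(1) > id_nonsyn) {   # nonsynonymous hit in B
        pos <- sample(1:2, 1)
        old <- substr(cod_b[i], pos, pos)
        substr(cod_b[i], pos, pos) <- sample(setdiff(nts, old), 1)
        prefix_intact[i] <- FALSE          # codon no longer qualifies
      }
    }
    # whole-codon gaps, alternating which sequence is gapped
    gap_in_a <- TRUE
    for (i in seq_len(n_codons)) {
      if (stats::runif(1) < gap_rate) {
        if (gap_in_a) cod_a[i] <- "---" else cod_b[i] <- "---"
        gap_in_a <- !gap_in_a
      }
    }
    pair <- aligned_cds_pair(paste(cod_a, collapse = ""),
                             paste(cod_b, collapse = ""), 0L)
    attr(pair, "truth") <- list(
      n_codons = n_codons, is_fourfold = is4,
      id_fourfold = id_fourfold, id_twofold = id_twofold,
      realised_fourfold = mean(third_cons[is4 & prefix_intact &
                                            cod_a != "---" &
                                            cod_b != "---"]))
    pair
  })
}

#' Simulate feature and peak interval sets with planted overlaps
#'
#' Places `n_features` non-overlapping features on a synthetic chromosome;
#' a chosen fraction receive an overlapping peak, and the remaining peaks
#' are placed in guaranteed-empty space downstream of all features, so the
#' overlapping feature count is known exactly.
#'
#' @param n_features,n_peaks set sizes; `n_peaks` must be at least the
#'   number of planted peaks.
#' @param planted_fraction fraction of features receiving a peak.
#' @param feature_length,peak_length interval lengths in bp.
#' @param seed integer seed.
#' @return list with `features`, `peaks` (both `GRanges`) and `truth`
#'   (logical vector: feature has a planted peak).
#' @export
simulate_intervals <- function(n_features, n_peaks, planted_fraction,
                               feature_length = 200L, peak_length = 300L,
                               seed = 1L) {
  n_planted <- round(planted_fraction * n_features)
  if (n_peaks < n_planted)
    stopf("need at least %d peaks to plant %d overlaps", n_planted,
          n_planted)
  slot <- feature_length + 2L * peak_length + 50L
  f_start <- (seq_len(n_features) - 1L) * slot + peak_length + 10L
  features <- genomic_intervals("chrS", f_start, f_start + feature_length,
                                name = paste0("feat", seq_len(n_features)))
  planted <- with_seed(seed, sample(n_features, n_planted))
  truth <- seq_len(n_features) %in% planted
  peaks <- list()
  if (n_planted > 0) {
    # peak overlapping the feature's first half
    ps <- f_start[planted] - peak_length %/% 2L
    peaks[[1]] <- genomic_intervals("chrS", ps, ps + peak_length)
  }
  n_bg <- n_peaks - n_planted
  if (n_bg > 0) {
    empty0 <- n_features * slot + 10L * peak_length
    bs <- empty0 + (seq_len(n_bg) - 1L) * (peak_length + 50L)
    peaks[[length(peaks) + 1]] <- genomic_intervals("chrS", bs,
                                                    bs + peak_length)
  }
  peaks <- if (length(peaks)) do.call(c, peaks)
  else genomic_intervals(character(), integer(), integer())
  list(features = features, peaks = peaks, truth = truth)
}
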