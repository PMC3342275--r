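#' Anatomy ontology, anatomy map and annotation tables
#'
#' Light containers for matching enhancer-call anatomies against curated
#' gene-expression annotations, emulating the structure of the ZFIN anatomy
#' ontology and wildtype-expression flat file.
#'
#' `ontology()` validates a parent/child term table: columns `term_id`,
#' `name`, `parent_id` (`NA` for roots; multiple parent rows per term
#' allowed). `anatomy_map()` maps each scored enhancer anatomy to one or
#' more seed ontology terms. `annotation_table()` validates gene expression
#' records (`gene_id`, `term_id`, `start_stage`, `end_stage`, `assay`,
#' `probe_quality`) against an ordered developmental stage list.
#'
#' @param terms,map,records data frames with the columns above.
#' @param stage_order character vector of stage names in developmental
#'   order; stage columns must draw from it.
#' @return the validated data frame, classed.
#' @export
ontology <- function(terms) {
  need <- c("term_id", "name", "parent_id")
  if (!all(need %in% names(terms)))
    stopf("ontology needs columns %s", paste(need, collapse = ", "))
  self <- !is.na(terms$parent_id) & terms$term_id == terms$parent_id
  if (any(self)) stopf("term '%s' is its own parent", terms$term_id[self][1])
  dup <- unique(terms[, c("term_id", "name")])
  if (anyDuplicated(dup$term_id))
    stopf("ontology term ids map to multiple names")
  class(terms) <- c("anatomy_ontology", "data.frame")
  terms
}

#' @rdname ontology
#' @export
anatomy_map <- function(map) {
  if (!all(c("anatomy", "term_id") %in% names(map)))
    stopf("anatomy map needs columns anatomy, term_id")
  class(map) <- c("anatomy_map", "data.frame")
  map
}

#' @rdname ontology
#' @export
annotation_table <- function(records, stage_order) {
  need <- c("gene_id", "term_id", "start_stage", "end_stage")
  if (!all(need %in% names(records)))
    stopf("annotation table needs columns %s", paste(need, collapse = ", "))
  bad <- !(records$start_stage %in% stage_order) |
    !(records$end_stage %in% stage_order)
  if (any(bad)) stopf("annotation stages not in the declared stage order")
  if (!"probe_quality" %in% names(records)) records$probe_quality <- NA_integer_
  pq <- records$probe_quality
  if (any(!is.na(pq) & (pq < 1 | pq > 5)))
    stopf("probe_quality must lie in 1..5")
  attr(records, "stage_order") <- stage_order
  class(records) <- c("annotation_table", "data.frame")
  records
}

#' Expand an enhancer anatomy to ontology terms
#'
#' Returns the seed term ids mapped to the anatomy plus all immediate
#' children of each seed -- exactly one sub-level down, never grandchildren.
#' The one-level expansion absorbs differences in annotation resolution
#' (e.g. a gene annotated in the telencephalon matches a forebrain call).
#'
#' @param anatomy scored anatomy name.
#' @param map an [anatomy_map()].
#' @param ont an [ontology()].
#' @return character vector of term ids.
#' @export
expand_terms <- function(anatomy, map, ont) {
  seeds <- map$term_id[map$anatomy == anatomy]
  if (length(seeds) == 0) stopf("anatomy '%s' not in the anatomy map", anatomy)
  children <- ont$term_id[!is.na(ont$parent_id) & ont$parent_id %in% seeds]
  unique(c(seeds, children))
}

# Do the stage intervals [s1,e1] and [s2,e2] intersect, in the declared
# stage order (closed intervals on stage indices)?
stages_intersect <- function(s1, e1, s2, e2, stage_order) {
  i <- function(x) match(x, stage_order)
  pmax(i(s1), i(s2)) <= pmin(i(e1), i(e2))
}

#' Stage window
#'
#' @param start_stage,end_stage stage names, start before or equal to end in
#'   `stage_order`.
#' @param stage_order ordered stage list.
#' @return classed list used by [gene_matches()].
#' @export
stage_window <- function(start_stage, end_stage, stage_order) {
  if (!(start_stage %in% stage_order) || !(end_stage %in% stage_order))
    stopf("window stages must be in the stage order")
  if (match(start_stage, stage_order) > match(end_stage, stage_order))
    stopf("window start stage after end stage")
  structure(list(start_stage = start_stage, end_stage = end_stage,
                 stage_order = stage_order), class = "stage_window")
}

#' Match a gene's annotated expression to enhancer anatomies
#'
#' An enhancer anatomy is matched when the gene has at least one annotation
#' record whose term falls in the one-level ontology expansion of the
#' anatomy and whose stage interval intersects the window.
#'
#' @param anatomies character vector of called anatomies (may be empty).
#' @param gene_id gene to look up.
#' @param table an [annotation_table()].
#' @param window a [stage_window()].
#' @param map,ont anatomy map and ontology.
#' @param min_probe_quality optional filter: keep only records with
#'   `probe_quality >= min_probe_quality` (NA quality dropped). Default
#'   `NULL` applies no filter.
#' @return character vector of matched anatomies; attribute `no_data` is
#'   TRUE when the gene has no records at all.
#' @export
gene_matches <- function(anatomies, gene_id, table, window, map, ont,
                         min_probe_quality = NULL) {
  rec <- table[table$gene_id == gene_id, , drop = FALSE]
  if (!is.null(min_probe_quality))
    rec <- rec[!is.na(rec$probe_quality) &
                 rec$probe_quality >= min_probe_quality, , drop = FALSE]
  out <- character()
  if (nrow(rec) > 0 && length(anatomies) > 0) {
    in_window <- stages_intersect(rec$start_stage, rec$end_stage,
                                  window$start_stage, window$end_stage,
                                  window$stage_order)
    rec <- rec[in_window, , drop = FALSE]
    for (a in anatomies) {
      if (any(rec$term_id %in% expand_terms(a, map, ont))) out <- c(out, a)
    }
  }
  attr(out, "no_data") <- nrow(table[table$gene_id == gene_id, ]) == 0
  out
}

# Extract the anatomy set from an enhancer_call or a plain character vector.
call_anatomy_set <- function(x) {
  if (inherits(x, "enhancer_call")) x$significant_anatomies else as.character(x)
}

#' Host vs neighboring gene expression overlap
#'
#' For each construct, tests whether its called anatomies overlap the
#' annotated expression of the host gene and of the nearest upstream and
#' downstream genes, then compares the host overlap rate against each
#' neighbor class with the one-sided two-proportion test (host greater).
#' Constructs whose gene has no annotation data are dropped from that
#' class's denominator.
#'
#' @param calls list of anatomy sets (character vectors) or
#'   [enhancer_call()] objects.
#' @param genes data frame with one row per call: columns `host`,
#'   `upstream`, `downstream` (gene ids, NA allowed).
#' @param table,window,map,ont as in [gene_matches()].
#' @return list with per-class `k`, `n`, and `p_vs_host` for the neighbor
#'   classes, plus the per-call logical match matrix.
#' @export
neighbor_comparison <- function(calls, genes, table, window, map, ont) {
  classes <- c("host", "upstream", "downstream")
  if (!all(classes %in% names(genes)))
    stopf("gene table needs columns host, upstream, downstream")
  if (nrow(genes) != length(calls)) stopf("one gene row per call required")
  sets <- lapply(calls, call_anatomy_set)
  match_mat <- matrix(NA, length(calls), length(classes),
                      dimnames = list(NULL, classes))
  for (j in classes) for (i in seq_along(calls)) {
    g <- genes[[j]][i]
    if (is.na(g)) next
    mm <- gene_matches(sets[[i]], g, table, window, map, ont)
    match_mat[i, j] <- if (attr(mm, "no_data")) NA else length(mm) >= 1
  }
  k <- colSums(match_mat, na.rm = TRUE)
  n <- colSums(!is.na(match_mat))
  p_vs_host <- vapply(c("upstream", "downstream"), function(j) {
    if (n["host"] < 1 || n[j] < 1) return(NA_real_)
    proportions_test(k["host"], n["host"], k[j], n[j])
  }, 0.0)
  list(k = k, n = n, p_vs_host = p_vs_host, matches = match_mat)
}

#' Random-gene permutation null for expression overlap
#'
#' How many of the constructs would overlap "their" gene's expression if
#' genes were assigned at random? Each iteration samples `n_genes` distinct
#' genes (uniformly, without replacement, from the annotation table minus
#' the exclusion set -- host/upstream/downstream genes and miRNA genes),
#' assigns one to each call, and counts calls whose assigned gene matches at
#' least one called anatomy. Returns the mean and sample standard deviation
#' of that count over `n_iter` iterations.
#'
#' @param calls list of anatomy sets or [enhancer_call()] objects; its
#'   length sets `n_genes` unless given.
#' @param table,window,map,ont as in [gene_matches()].
#' @param exclusions character vector of gene ids never sampled.
#' @param n_genes genes per iteration (default `length(calls)`).
#' @param n_iter iterations (default 100).
#' @param seed integer seed.
#' @return list with `mean`, `sd`, and the per-iteration `counts`.
#' @export
random_gene_null <- function(calls, table, window, map, ont,
                             exclusions = character(),
                             n_genes = length(calls), n_iter = 100L,
                             seed = 1L) {
  sets <- lapply(calls, call_anatomy_set)
  pool <- setdiff(unique(table$gene_id), exclusions)
  if (length(pool) < n_genes)
    stopf("only %d eligible genes for %d-gene samples", length(pool), n_genes)
  if (n_genes != length(sets))
    stopf("one sampled gene per call required")
  # precompute gene -> matched? per call (match depends only on (gene, call))
  counts <- with_seed(seed, {
    vapply(seq_len(n_iter), function(it) {
      g <- sample(pool, n_genes)
      sum(vapply(seq_along(sets), function(i) {
        length(gene_matches(sets[[i]], g[i], table, window, map, ont)) >= 1
      }, FALSE))
    }, 0L)
  })
  list(mean = mean(counts), sd = stats::sd(counts), counts = counts)
}
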