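#' Binary embryo-by-anatomy expression matrix
#'
#' The atom of all calling statistics: one row per surviving scored embryo,
#' one 0/1 column per anatomy, with the injection batch recorded per embryo.
#' Embryos with no expression anywhere are retained as all-zero rows; the
#' denominators of all proportions are surviving embryos, not expressing
#' embryos.
#'
#' @param data integer/logical matrix (embryos x anatomies), values 0/1.
#' @param vocab an [anatomy_vocabulary()]; its size must equal `ncol(data)`.
#' @param construct_id construct label, e.g. `"CCE-odz3"` or `"control"`.
#' @param batch_id character vector of injection-round labels, recycled.
#' @param embryo_id optional integer ids; defaults to row order.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(data, vocab = default_vocabulary(),
                              construct_id = "construct",
                              batch_id = "batch1", embryo_id = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "integer"
  if (ncol(data) != nrow(vocab))
    stopf("matrix has %d columns but vocabulary has %d anatomies",
          ncol(data), nrow(vocab))
  if (length(data) && !all(data %in% c(0L, 1L)))
    stopf("expression matrix entries must be 0 or 1")
  colnames(data) <- vocab$name
  n <- nrow(data)
  batch_id <- rep_len(as.character(batch_id), max(n, 0L))
  embryo_id <- if (is.null(embryo_id)) seq_len(n) else as.integer(embryo_id)
  structure(list(construct_id = as.character(construct_id),
                 vocabulary = vocab, data = data,
                 batch_id = batch_id, embryo_id = embryo_id),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix '%s': %d embryos x %d anatomies (%d batch%s)\n",
              x$construct_id, n_embryos(x), ncol(x$data),
              length(unique(x$batch_id)),
              if (length(unique(x$batch_id)) == 1) "" else "es"))
  if (n_embryos(x) > 0) {
    p <- round(colMeans(x$data), 3)
    cat("Expressing fraction per anatomy:\n")
    print(p)
  }
  invisible(x)
}

#' @rdname expression_matrix
#' @param x an `expression_matrix`.
#' @export
n_embryos <- function(x) nrow(x$data)

#' Merge injection batches of one construct
#'
#' Constructs were typically injected in two separate rounds on different
#' days; batches are concatenated with their batch labels preserved so that
#' per-round structure stays visible to the resampling criterion.
#'
#' @param matrices list of [expression_matrix()] objects sharing
#'   `construct_id` and vocabulary.
#' @return a single merged `expression_matrix`.
#' @export
merge_batches <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  ref <- matrices[[1]]
  for (m in matrices[-1]) {
    if (!identical(m$vocabulary$name, ref$vocabulary$name))
      stopf("cannot merge batches with different anatomy vocabularies")
    if (!identical(m$construct_id, ref$construct_id))
      stopf("cannot merge batches from different constructs ('%s' vs '%s')",
            ref$construct_id, m$construct_id)
  }
  expression_matrix(
    do.call(rbind, lapply(matrices, function(m) m$data)),
    vocab = ref$vocabulary, construct_id = ref$construct_id,
    batch_id = unlist(lapply(matrices, function(m) m$batch_id)),
    embryo_id = seq_len(sum(vapply(matrices, n_embryos, 0L))))
}

#' Write / read an expression matrix as TSV
#'
#' Columns: `construct_id`, `batch_id`, `embryo_id`, then one 0/1 column per
#' anatomy (header = anatomy names). The round trip is lossless.
#'
#' @param m an [expression_matrix()].
#' @param path file path.
#' @param vocab vocabulary used to validate the header on read; defaults to
#'   reconstructing the vocabulary from the header.
#' @return `read_matrix` returns an `expression_matrix`; `write_matrix`
#'   returns `path` invisibly.
#' @export
write_matrix <- function(m, path) {
  d <- data.frame(construct_id = m$construct_id, batch_id = m$batch_id,
                  embryo_id = m$embryo_id, check.names = FALSE,
                  stringsAsFactors = FALSE)
  d <- cbind(d, as.data.frame(m$data, check.names = FALSE))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path, vocab = NULL) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(d) == 0 || ncol(d) < 4)
    stopf("matrix file '%s' is empty or malformed", path)
  meta <- c("construct_id", "batch_id", "embryo_id")
  if (!all(meta %in% names(d)))
    stopf("matrix file must have columns %s", paste(meta, collapse = ", "))
  anat <- setdiff(names(d), meta)
  if (is.null(vocab)) vocab <- anatomy_vocabulary(anat)
  if (!identical(anat, vocab$name))
    stopf("matrix header anatomies do not match the vocabulary")
  cells <- as.matrix(d[, anat, drop = FALSE])
  if (!all(cells %in% c(0, 1)))
    stopf("non-binary cell values in '%s'", path)
  expression_matrix(cells, vocab = vocab,
                    construct_id = d$construct_id[1],
                    batch_id = d$batch_id, embryo_id = d$embryo_id)
}
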