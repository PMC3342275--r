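#' Parse a controlled-vocabulary scoring transcript
#'
#' Converts the text output of voice-dictated embryo scoring into a binary
#' [expression_matrix()]. The transcript is a whitespace-separated token
#' stream in which a delimiter token (default `"new"`) starts a new embryo
#' and each embryo lists zero or more anatomy tokens -- numeric codes,
#' canonical names, or synonyms, case-insensitively. An embryo dictated with
#' no anatomies (consecutive delimiters) is retained as an all-zero record:
#' it survived scoring and counts toward the denominator. Repeating an
#' anatomy within one embryo is idempotent.
#'
#' @param text transcript as a single string or character vector of lines.
#' @param vocab an [anatomy_vocabulary()].
#' @param policy `"strict"` aborts on the first unrecognized token, with its
#'   position; `"skip"` ignores unrecognized tokens (they are reported via a
#'   `"skipped_tokens"` attribute).
#' @param delimiter embryo delimiter token.
#' @param construct_id,batch_id labels attached to the resulting matrix.
#' @return an [expression_matrix()] with one row per embryo segment.
#' @examples
#' m <- parse_transcript("new 1 6 new new 3", construct_id = "demo")
#' n_embryos(m)      # 3
#' m$data[1, c(1, 6)] # forebrain + notochord
#' @export
parse_transcript <- function(text, vocab = default_vocabulary(),
                             policy = c("strict", "skip"),
                             delimiter = "new",
                             construct_id = "construct",
                             batch_id = "batch1") {
  policy <- match.arg(policy)
  toks <- unlist(strsplit(tolower(paste(text, collapse = " ")), "[[:space:]]+"))
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0) stopf("empty transcript")
  lookup <- vocab_lookup(vocab)
  is_delim <- toks == tolower(delimiter)
  if (!any(is_delim)) stopf("transcript contains no '%s' embryo delimiter",
                            delimiter)
  skipped <- character()
  seg <- cumsum(is_delim)          # 0 = before first embryo
  for (i in which(seg == 0)) {
    if (policy == "strict")
      stopf("token '%s' at position %d precedes the first embryo delimiter",
            toks[i], i)
    skipped <- c(skipped, sprintf("%d:%s", i, toks[i]))
  }
  n_emb <- max(seg)
  m <- matrix(0L, n_emb, nrow(vocab))
  body <- which(!is_delim & seg > 0)
  for (i in body) {
    code <- lookup[toks[i]]
    if (is.na(code)) {
      if (policy == "strict")
        stopf("unrecognized token '%s' at position %d (embryo %d)",
              toks[i], i, seg[i])
      skipped <- c(skipped, sprintf("%d:%s", i, toks[i]))
    } else {
      m[seg[i], code] <- 1L
    }
  }
  out <- expression_matrix(m, vocab = vocab, construct_id = construct_id,
                           batch_id = batch_id)
  attr(out, "skipped_tokens") <- skipped
  out
}
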