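#' Anatomy scoring vocabulary
#'
#' The controlled vocabulary used when dictating GFP expression calls at the
#' microscope: each scored anatomical region has a small numeric code, a
#' canonical name, and a set of dictation synonyms. The default vocabulary
#' covers the ten regions scored in 22--30 hpf zebrafish embryos, coded 1--10
#' in the conventional reporting order (forebrain first, tail region last).
#'
#' @param names character vector of canonical anatomy names.
#' @param synonyms list of character vectors, one per anatomy, of accepted
#'   alternative tokens (case-insensitive). May be `NULL`.
#' @return an object of class `anatomy_vocabulary`: a data frame with columns
#'   `code`, `name` and a list column `synonyms`.
#' @examples
#' vocab <- default_vocabulary()
#' vocab$name
#' @export
anatomy_vocabulary <- function(names, synonyms = NULL) {
  names <- as.character(names)
  if (anyDuplicated(names)) stopf("canonical anatomy names must be unique")
  if (length(names) < 1) stopf("vocabulary must contain at least one anatomy")
  if (is.null(synonyms)) synonyms <- rep(list(character()), length(names))
  if (length(synonyms) != length(names))
    stopf("need one synonym set per anatomy")
  v <- data.frame(code = seq_along(names), name = names,
                  stringsAsFactors = FALSE)
  v$synonyms <- lapply(synonyms, as.character)
  class(v) <- c("anatomy_vocabulary", "data.frame")
  v
}

#' @rdname anatomy_vocabulary
#' @export
default_vocabulary <- function() {
  anatomy_vocabulary(
    names = c("Forebrain", "Midbrain/Hindbrain", "Eye", "Ear/AboveHeart",
              "Heart", "Notochord", "Yolk/YolkExtension",
              "MidTrunk/AboveYolk", "Muscle", "TailRegion"),
    synonyms = list(
      c("forebrain", "fb"),
      c("midbrain", "hindbrain", "midhindbrain", "mhb"),
      c("eye"),
      c("ear", "aboveheart", "otic"),
      c("heart"),
      c("notochord", "noto"),
      c("yolk", "yolkextension"),
      c("midtrunk", "aboveyolk", "trunk"),
      c("muscle", "somite"),
      c("tail", "tailregion")
    )
  )
}

#' Read a vocabulary file
#'
#' TSV with columns `code`, `name`, `synonyms` (comma-separated, may be
#' empty). Codes must be contiguous from 1 in file order.
#'
#' @param path file path.
#' @return an [anatomy_vocabulary()].
#' @export
read_vocabulary <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("code", "name") %in% names(d)))
    stopf("vocabulary file needs 'code' and 'name' columns")
  d <- d[order(d$code), , drop = FALSE]
  if (!identical(as.integer(d$code), seq_len(nrow(d))))
    stopf("vocabulary codes must be contiguous from 1")
  syn <- if ("synonyms" %in% names(d)) {
    lapply(strsplit(ifelse(is.na(d$synonyms), "", d$synonyms), ","),
           function(s) trimws(s[nzchar(trimws(s))]))
  } else NULL
  anatomy_vocabulary(d$name, syn)
}

# Lookup table token -> code for a vocabulary (lower-cased tokens).
vocab_lookup <- function(vocab) {
  toks <- c(as.character(vocab$code), tolower(vocab$name),
            unlist(lapply(seq_len(nrow(vocab)), function(i)
              tolower(vocab$synonyms[[i]]))))
  codes <- c(vocab$code, vocab$code,
             unlist(lapply(seq_len(nrow(vocab)), function(i)
               rep(vocab$code[i], length(vocab$synonyms[[i]])))))
  stats::setNames(codes, toks)
}

#' @export
print.anatomy_vocabulary <- function(x, ...) {
  cat("Anatomy vocabulary (", nrow(x), " regions)\n", sep = "")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %2d  %s\n", x$code[i], x$name[i]))
  invisible(x)
}
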