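#' Run code with a temporary RNG state
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's random
#' number generator state afterwards, so package internals never clobber a
#' user's simulation stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# Deterministic substream seed from a pipeline seed plus arbitrary labels.
# Keeps results reproducible per (construct, anatomy, run) without the
# substreams being trivially correlated. Result always fits in a 32-bit int.
derive_seed <- function(seed, ...) {
  labels <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (cc in utf8ToInt(labels)) h <- (h * 31 + cc) %% 2147483563
  as.integer(h + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
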