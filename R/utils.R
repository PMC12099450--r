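## Internal helpers shared across modules.

#' @importFrom methods is
#' @importFrom utils head tail read.table write.table
NULL

## All internal genomic coordinates are 0-based half-open [start, end).
## User-facing reports are 1-based inclusive; these two helpers are the only
## place the conversion happens.
to1 <- function(pos0) pos0 + 1L
## end of a half-open interval already equals the 1-based position of the
## last included base, so interval [s, e) prints as (s + 1, e).

#' Evaluate an expression under a fixed RNG seed, restoring the RNG state
#'
#' Used for deterministic artifacts that must not consume (or depend on) the
#' caller's RNG stream, e.g. the bundled mini-reference sequences of presets.
#' @keywords internal
with_fixed_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
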