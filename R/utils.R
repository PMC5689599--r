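# Shared helpers: symbol canonicalization and seed-scoped RNG.

#' Canonicalize gene symbols
#'
#' Gene identifiers from GWAS/OMIM tables, STRING dumps and GMT files mix
#' upper and lower case; all ingest paths funnel through this so that joins
#' across sources are by canonical (upper-case, trimmed) symbol.
#'
#' @param x character vector of gene symbols.
#' @return character vector, trimmed and upper-cased.
#' @export
canonical_symbol <- function(x) {
  toupper(trimws(as.character(x)))
}

# Run `expr` under a local RNG stream derived from `seed`, restoring the
# caller's RNG state afterwards. All package randomness flows through here so
# results are reproducible from a single integer seed and never disturb the
# session RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a parent seed and an index, staying inside the
# 32-bit integer range.
child_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 16807) %% 2147483647)
}
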