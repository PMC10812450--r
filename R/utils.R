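#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a private RNG stream, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Canonical form for compound names: trim, collapse whitespace, map
# typographic characters (non-breaking space, en/em dash, primes) to ASCII.
# Matching is exact after this normalisation; no fuzzy matching, so a
# misspelled compound fails loudly instead of being silently misclassified.
normalize_name <- function(x) {
  x <- enc2utf8(as.character(x))
  x <- gsub(" ", " ", x, useBytes = FALSE)
  x <- gsub("[‐‑‒–—−]", "-", x)
  x <- gsub("[′″“”‘’]", "", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

# Stable id for a row/column position used in parser error messages.
cell_ref <- function(row, col) sprintf("row '%s', column '%s'", row, col)
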