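#' @import methods
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Normalize a vocabulary term
#'
#' Terms (drug substance names, MedDRA preferred terms) are stored and
#' matched in a single canonical form: surrounding whitespace stripped and
#' upper-case folded. openFDA reaction PTs are conventionally upper case
#' while user input is mixed case; matching is exact on the normalized
#' string — no fuzzy matching and no drugname cleaning.
#'
#' @param x character vector of terms.
#' @return character vector of normalized terms, duplicates removed,
#'   empties dropped.
#' @export
normalizeTerms <- function(x) {
  if (is.null(x) || length(x) == 0L) return(character(0))
  x <- toupper(trimws(as.character(x)))
  x <- x[nzchar(x) & !is.na(x)]
  unique(x)
}

# logging contract: messages to stderr gated by option(faersSignal.verbose)
vigilLog <- function(..., level = "info") {
  verbose <- getOption("faersSignal.verbose", "warn")
  levels <- c(debug = 1L, info = 2L, warn = 3L)
  if (levels[[level]] >= levels[[verbose]]) {
    message(sprintf("[%s] %s", level, paste0(...)))
  }
  invisible(NULL)
}
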