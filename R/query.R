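#' Construct a report query
#'
#' All terms are normalized (trimmed, upper-cased) on construction, so
#' matching is case-insensitive from the caller's point of view while the
#' engine itself compares exact strings.
#'
#' @param drugAll,drugNone substance names that must all be present /
#'   absent.
#' @param reactionAll,reactionNone reaction preferred terms, analogous.
#' @param indicationAll,indicationNone indication preferred terms,
#'   analogous.
#' @return a \linkS4class{ReportQuery}.
#' @examples
#' reportQuery(drugAll = "paroxetine", reactionAll = "DEPRESSION")
#' @export
reportQuery <- function(drugAll = character(0), drugNone = character(0),
                        reactionAll = character(0), reactionNone = character(0),
                        indicationAll = character(0), indicationNone = character(0)) {
  new("ReportQuery",
      drugAll = normalizeTerms(drugAll), drugNone = normalizeTerms(drugNone),
      reactionAll = normalizeTerms(reactionAll),
      reactionNone = normalizeTerms(reactionNone),
      indicationAll = normalizeTerms(indicationAll),
      indicationNone = normalizeTerms(indicationNone))
}

#' @rdname reportQuery
#' @param query a \linkS4class{ReportQuery}.
#' @return \code{queryIsEmpty}: TRUE when no slot constrains anything (such
#'   a query matches every report).
#' @export
queryIsEmpty <- function(query) {
  all(vapply(slotNames(query), function(s) length(slot(query, s)) == 0L,
             logical(1)))
}

# conjunction of two queries (used to fold masks into queries)
queryAnd <- function(a, b) {
  if (is.null(b)) return(a)
  new("ReportQuery",
      drugAll = union(a@drugAll, b@drugAll),
      drugNone = union(a@drugNone, b@drugNone),
      reactionAll = union(a@reactionAll, b@reactionAll),
      reactionNone = union(a@reactionNone, b@reactionNone),
      indicationAll = union(a@indicationAll, b@indicationAll),
      indicationNone = union(a@indicationNone, b@indicationNone))
}

setMethod("show", "ReportQuery", function(object) {
  parts <- character(0)
  for (s in slotNames(object)) {
    v <- slot(object, s)
    if (length(v)) parts <- c(parts, sprintf("%s={%s}", s, paste(v, collapse = ",")))
  }
  cat("ReportQuery:", if (length(parts)) paste(parts, collapse = " ") else "<match all>", "\n")
})
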