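#' Count reports matching a query
#'
#' The fundamental counting primitive behind every contingency-table cell.
#' With a \code{mask} the backend is first restricted to reports matching
#' the mask, then \code{query} is applied; for conjunctive queries this is
#' identical to counting \code{query AND mask}. Masks are how background
#' correction (restriction to a therapeutic area / indication) is expressed.
#'
#' @param backend a \linkS4class{ReportStore} or \linkS4class{RemoteBackend}.
#' @param query a \linkS4class{ReportQuery}.
#' @param mask optional \linkS4class{ReportQuery} restricting the population.
#' @return a single non-negative integer report count.
#' @export
setGeneric("countReports", function(backend, query = reportQuery(), mask = NULL)
  standardGeneric("countReports"))

#' Enumerate terms of a field with report counts
#'
#' Lists every term of the given field occurring in at least one matching
#' report, with the number of reports carrying it (a report contributes at
#' most 1 per term however often the term repeats inside it). Sorted by
#' count descending, ties by ascending lexicographic term order.
#'
#' @param backend a \linkS4class{ReportStore} or \linkS4class{RemoteBackend}.
#' @param field one of \code{"drug"}, \code{"reaction"}, \code{"indication"}.
#' @param restrict optional \linkS4class{ReportQuery}; only reports matching
#'   it are scanned.
#' @return data.frame with columns \code{term}, \code{count}; for remote
#'   backends an attribute \code{truncated} flags the service's 100-term cap.
#' @export
setGeneric("listTerms", function(backend, field, restrict = NULL)
  standardGeneric("listTerms"))

#' @rdname tableCells
#' @export
setGeneric("tableCells", function(x) standardGeneric("tableCells"))

#' @rdname tableCells
#' @export
setGeneric("tableMargins", function(x) standardGeneric("tableMargins"))

#' @rdname dpaMeasures
#' @export
setGeneric("reportingRate", function(x) standardGeneric("reportingRate"))

#' @rdname dpaMeasures
#' @export
setGeneric("ror", function(x) standardGeneric("ror"))

#' @rdname dpaMeasures
#' @export
setGeneric("prr", function(x) standardGeneric("prr"))

#' @rdname dpaMeasures
#' @export
setGeneric("rrr", function(x) standardGeneric("rrr"))

#' @rdname dpaMeasures
#' @export
setGeneric("chisqYates", function(x, clamp = TRUE) standardGeneric("chisqYates"))

#' @rdname evansSignal
#' @export
setGeneric("evansSignal", function(x, prrMin = 2, chi2Min = 4, deMin = 3)
  standardGeneric("evansSignal"))
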