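buildIndex <- function(ids, fieldList) {
  env <- new.env(parent = emptyenv(), hash = TRUE)
  lens <- lengths(fieldList)
  if (sum(lens)) {
    terms <- unlist(fieldList, use.names = FALSE)
    pos <- rep.int(seq_along(fieldList), lens)
    sp <- split(pos, terms)
    for (t in names(sp)) assign(t, sp[[t]], envir = env)
  }
  env
}

#' Construct a report store from parallel field lists
#'
#' The lower-level constructor behind [loadOpenfdaJson()] and
#' [generateReports()]. Term vectors are normalized and de-duplicated per
#' report; inverted indexes are built eagerly.
#'
#' @param reportId character vector of unique, non-empty identifiers.
#' @param drugs,reactions,indications lists of character vectors parallel
#'   to \code{reportId} (recycled from empty when omitted).
#' @param uncleaned logical vector flagging reports whose drug names are
#'   verbatim product names rather than cleaned substance names.
#' @return a \linkS4class{ReportStore}.
#' @examples
#' reportStore(c("1", "2"),
#'             drugs = list("aspirin", c("aspirin", "warfarin")),
#'             reactions = list("RASH", character(0)))
#' @export
reportStore <- function(reportId, drugs = NULL, reactions = NULL,
                        indications = NULL, uncleaned = NULL) {
  n <- length(reportId)
  blank <- replicate(n, character(0), simplify = FALSE)
  norm <- function(x) {
    if (is.null(x)) return(blank)
    stopifnot(length(x) == n)
    lapply(x, normalizeTerms)
  }
  drugs <- norm(drugs); reactions <- norm(reactions); indications <- norm(indications)
  idx <- new.env(parent = emptyenv())
  idx$drug <- buildIndex(reportId, drugs)
  idx$reaction <- buildIndex(reportId, reactions)
  idx$indication <- buildIndex(reportId, indications)
  new("ReportStore", reportId = as.character(reportId),
      drugs = drugs, reactions = reactions, indications = indications,
      uncleaned = if (is.null(uncleaned)) logical(n) else uncleaned,
      index = idx)
}

#' @rdname reportStore
#' @param x,object a \linkS4class{ReportStore}.
#' @export
setMethod("length", "ReportStore", function(x) length(x@reportId))

setMethod("show", "ReportStore", function(object) {
  cat(sprintf("ReportStore with %d reports (%d distinct drugs, %d reactions, %d indications; %d uncleaned)\n",
              length(object), length(ls(object@index$drug)),
              length(ls(object@index$reaction)), length(ls(object@index$indication)),
              sum(object@uncleaned)))
})

#' Accessors for report fields
#'
#' @param store a \linkS4class{ReportStore}.
#' @return \code{reportIds}: character vector; the field accessors return
#'   lists of character vectors parallel to it.
#' @export
reportIds <- function(store) store@reportId

#' @rdname reportIds
#' @export
reportDrugs <- function(store) store@drugs

#' @rdname reportIds
#' @export
reportReactions <- function(store) store@reactions

#' @rdname reportIds
#' @export
reportIndications <- function(store) store@indications

#' Drop reports without any drug term
#'
#' Reports without a cleaned drugname stay in a store by default and count
#' toward N, d and e — unprocessed records distort the complementary
#' numbers of every contingency calculation, and both policies need to be
#' testable. This derives the store under the opposite policy.
#'
#' @param store a \linkS4class{ReportStore}.
#' @return a new store containing only reports with a non-empty drug set.
#' @export
dropUndrugged <- function(store) {
  keep <- lengths(store@drugs) > 0L
  reportStore(store@reportId[keep], store@drugs[keep], store@reactions[keep],
              store@indications[keep], store@uncleaned[keep])
}

fieldIndex <- function(store, field) {
  if (!field %in% c("drug", "reaction", "indication"))
    stop("unknown field: ", field, " (expected drug, reaction or indication)")
  store@index[[field]]
}

fieldList <- function(store, field) {
  switch(field, drug = store@drugs, reaction = store@reactions,
         indication = store@indications,
         stop("unknown field: ", field, " (expected drug, reaction or indication)"))
}

indexLookup <- function(idx, term) {
  v <- get0(term, envir = idx, inherits = FALSE)
  if (is.null(v)) integer(0) else v
}

# integer positions of reports matching a query, optionally within a
# candidate position set
matchingPositions <- function(store, query, candidates = NULL) {
  pos <- candidates %||% seq_len(length(store))
  for (f in c("drug", "reaction", "indication")) {
    idx <- store@index[[f]]
    for (t in slot(query, paste0(f, "All"))) {
      pos <- intersect(pos, indexLookup(idx, t))
      if (!length(pos)) return(integer(0))
    }
    for (t in slot(query, paste0(f, "None")))
      pos <- setdiff(pos, indexLookup(idx, t))
  }
  pos
}

#' @rdname countReports
setMethod("countReports", "ReportStore", function(backend, query = reportQuery(),
                                                  mask = NULL) {
  pos <- NULL
  if (!is.null(mask)) pos <- matchingPositions(backend, mask)
  length(matchingPositions(backend, query, pos))
})

#' @rdname listTerms
setMethod("listTerms", "ReportStore", function(backend, field, restrict = NULL) {
  fl <- fieldList(backend, field)
  pos <- if (is.null(restrict)) seq_len(length(backend))
         else matchingPositions(backend, restrict)
  terms <- unlist(fl[pos], use.names = FALSE)
  if (!length(terms)) {
    out <- data.frame(term = character(0), count = integer(0))
  } else {
    tab <- table(terms)
    out <- data.frame(term = names(tab), count = as.integer(tab))
    out <- out[order(-out$count, out$term), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "truncated") <- FALSE
  out
})
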