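FIELD_MAP <- c(drug = "patient.drug.openfda.substance_name",
               reaction = "patient.reaction.reactionmeddrapt",
               indication = "patient.drug.drugindication")

#' An openFDA API request
#'
#' Validated container for the request parameters of the drug-event
#' endpoint. The public service caps \code{limit} at 100 and \code{skip}
#' at 5000 (so at most 5100 reports are retrievable per search, and count
#' lists at 100 terms); those caps are enforced here.
#'
#' @param search search expression in the service's Lucene-like dialect
#'   (non-empty for analytic queries; \code{NULL} requests the whole
#'   collection's total).
#' @param count field name to aggregate counts over, or \code{NULL}.
#' @param limit,skip pagination parameters.
#' @return a named list of class \code{apiQuery}.
#' @export
apiQuery <- function(search = NULL, count = NULL, limit = 1L, skip = 0L) {
  if (limit > 100L) stop("openFDA caps limit at 100")
  if (skip > 5000L) stop("openFDA caps skip at 5000")
  if (limit < 1L || skip < 0L) stop("invalid pagination parameters")
  structure(list(search = search, count = count,
                 limit = as.integer(limit), skip = as.integer(skip)),
            class = "apiQuery")
}

renderTerm <- function(field, term, exact) {
  sprintf('%s%s:"%s"', FIELD_MAP[[field]], if (exact) ".exact" else "",
          tolower(term))
}

#' Render a query as an openFDA search string
#'
#' Deterministic: terms are sorted within each field, fields emitted in
#' drug, reaction, indication order, required groups first and negations
#' last. Every term is field-qualified and quoted (so multi-word preferred
#' terms survive), conjunctions join with \code{+AND+} and negations
#' render as \code{+AND+NOT+(field:"term")}. Reaction and indication
#' terms use the \code{.exact} field variants by default, substance names
#' do not.
#'
#' @param query a non-empty \linkS4class{ReportQuery}; the query must have
#'   at least one required term (an unconstrained or purely negative
#'   search is an API misuse).
#' @param exactReaction,exactIndication use the \code{.exact} variants.
#' @return a single search string.
#' @examples
#' buildSearchString(reportQuery(drugAll = c("diazepam", "haloperidol"),
#'                               reactionAll = "pain"))
#' @export
buildSearchString <- function(query, exactReaction = TRUE,
                              exactIndication = TRUE) {
  if (queryIsEmpty(query)) stop("cannot build a search string from an empty query")
  exact <- c(drug = FALSE, reaction = exactReaction, indication = exactIndication)
  groups <- character(0)
  for (f in c("drug", "reaction", "indication")) {
    terms <- sort(slot(query, paste0(f, "All")))
    if (!length(terms)) next
    rendered <- vapply(terms, renderTerm, character(1), field = f,
                       exact = exact[[f]])
    groups <- c(groups, if (length(rendered) > 1L)
      paste0("(", paste(rendered, collapse = "+AND+"), ")") else rendered)
  }
  if (!length(groups))
    stop("query has no required terms; a purely negative search cannot be expressed")
  out <- paste(groups, collapse = "+AND+")
  for (f in c("drug", "reaction", "indication")) {
    for (t in sort(slot(query, paste0(f, "None"))))
      out <- paste0(out, "+AND+NOT+(", renderTerm(f, t, exact[[f]]), ")")
  }
  out
}

#' Create a remote counting backend
#'
#' The returned backend satisfies the [countReports()] / [listTerms()]
#' contract of a local \linkS4class{ReportStore}, so every analysis in the
#' package runs unchanged against it. Counts come from a directory of
#' recorded responses (bit-reproducible; see [recordFixtures()]) and/or a
#' live endpoint; when both are given the fixture directory is consulted
#' first.
#'
#' @param endpoint base URL of the drug-event endpoint, e.g.
#'   \code{"https://api.fda.gov/drug/event.json"} ("" for fixture-only).
#' @param fixtureDir directory of recorded responses ("" for live-only).
#' @param apiKey optional API key for live requests.
#' @param exactReaction,exactIndication see [buildSearchString()].
#' @return a \linkS4class{RemoteBackend}.
#' @export
remoteStore <- function(endpoint = "", fixtureDir = "", apiKey = "",
                        exactReaction = TRUE, exactIndication = TRUE) {
  if (!nzchar(endpoint) && !nzchar(fixtureDir))
    stop("either a live endpoint or a fixture directory is required")
  if (nzchar(fixtureDir) && !dir.exists(fixtureDir))
    stop("fixture directory does not exist: ", fixtureDir)
  new("RemoteBackend", endpoint = endpoint, fixtureDir = fixtureDir,
      apiKey = apiKey, exactReaction = exactReaction,
      exactIndication = exactIndication)
}

setMethod("show", "RemoteBackend", function(object) {
  cat("RemoteBackend:",
      if (nzchar(object@fixtureDir)) paste0("fixtures at ", object@fixtureDir)
      else "", if (nzchar(object@endpoint)) paste0("live ", object@endpoint)
      else "", "\n")
})

requestKey <- function(search, count = NULL) {
  paste0(if (is.null(count)) "total" else paste0("count:", count),
         ":", search %||% "")
}

readFixtureIndex <- function(dir) {
  idx <- file.path(dir, "index.json")
  if (!file.exists(idx)) return(list())
  jsonlite::fromJSON(idx, simplifyVector = FALSE)
}

fixtureResponse <- function(backend, key) {
  if (!nzchar(backend@fixtureDir)) return(NULL)
  index <- readFixtureIndex(backend@fixtureDir)
  f <- index[[key]]
  if (is.null(f)) return(NULL)
  jsonlite::fromJSON(file.path(backend@fixtureDir, f), simplifyVector = FALSE)
}

liveResponse <- function(backend, search, count = NULL, retries = 3L) {
  params <- c(
    if (!is.null(search) && nzchar(search)) paste0("search=", search),
    if (!is.null(count)) paste0("count=", count),
    if (nzchar(backend@apiKey)) paste0("api_key=", backend@apiKey))
  full <- paste0(backend@endpoint,
                 if (length(params)) paste0("?", paste(params, collapse = "&")))
  vigilLog("GET ", full, level = "info")
  for (attempt in seq_len(retries + 1L)) {
    res <- tryCatch({
      con <- url(full, open = "rb")
      on.exit(close(con), add = TRUE)
      jsonlite::fromJSON(rawToChar(readBin(con, "raw", 1e7)),
                         simplifyVector = FALSE)
    }, error = function(e) e)
    if (!inherits(res, "error")) return(res)
    # the service answers zero-match searches with HTTP 404 + error body;
    # url() raises on 404, so retry only transient-looking failures
    if (attempt <= retries) Sys.sleep(2^(attempt - 1L))
  }
  stop("transport error querying ", backend@endpoint, ": ",
       conditionMessage(res), call. = FALSE)
}

fetchResponse <- function(backend, search, count = NULL) {
  key <- requestKey(search, count)
  resp <- fixtureResponse(backend, key)
  if (is.null(resp)) {
    if (!nzchar(backend@endpoint))
      stop("no recorded fixture for request '", key,
           "' and no live endpoint configured", call. = FALSE)
    resp <- liveResponse(backend, search, count)
  }
  resp
}

isNoMatches <- function(resp) {
  !is.null(resp$error) && identical(resp$error$code, "NOT_FOUND")
}

#' Fetch a term/count aggregation
#'
#' Parses the \code{results} array of term/count objects. The service
#' returns at most 100 terms per count request; a response of exactly 100
#' terms is flagged as (potentially) truncated — associations below
#' roughly the 100th rank are silently missing from such lists. The
#' service answers zero-match searches with an HTTP 404 error body, which
#' is treated as an empty list, not as an error.
#'
#' @param backend a \linkS4class{RemoteBackend}.
#' @param query an [apiQuery()] with a non-null \code{count} field.
#' @return data.frame(term, count) with attribute \code{truncated}.
#' @export
fetchCount <- function(backend, query) {
  stopifnot(inherits(query, "apiQuery"), !is.null(query$count))
  resp <- fetchResponse(backend, query$search, query$count)
  if (isNoMatches(resp)) {
    out <- data.frame(term = character(0), count = integer(0))
    attr(out, "truncated") <- FALSE
    return(out)
  }
  if (is.null(resp$results))
    stop("schema mismatch: count response without 'results'", call. = FALSE)
  out <- data.frame(
    term = toupper(vapply(resp$results, function(r) as.character(r$term),
                          character(1))),
    count = vapply(resp$results, function(r) as.integer(r$count), integer(1)))
  attr(out, "truncated") <- nrow(out) >= 100L
  out
}

#' Fetch the total number of matching reports
#'
#' Reads \code{meta.results.total} — the count feeding N, D, E and DE.
#'
#' @param backend a \linkS4class{RemoteBackend}.
#' @param search a search string, or \code{NULL} for the whole collection.
#' @return a single non-negative integer.
#' @export
fetchTotal <- function(backend, search = NULL) {
  resp <- fetchResponse(backend, search)
  if (isNoMatches(resp)) return(0L)
  total <- resp$meta$results$total
  if (is.null(total) || is.na(suppressWarnings(as.numeric(total))))
    stop("schema mismatch: response without meta.results.total", call. = FALSE)
  as.integer(total)
}

#' @rdname countReports
setMethod("countReports", "RemoteBackend",
          function(backend, query = reportQuery(), mask = NULL) {
  q <- queryAnd(query, mask)
  if (queryIsEmpty(q)) return(fetchTotal(backend, NULL))
  fetchTotal(backend, buildSearchString(q, backend@exactReaction,
                                        backend@exactIndication))
})

#' @rdname listTerms
setMethod("listTerms", "RemoteBackend", function(backend, field, restrict = NULL) {
  base <- FIELD_MAP[field]
  if (is.na(base)) stop("unknown field: ", field)
  countField <- paste0(base, ".exact")
  search <- if (is.null(restrict) || queryIsEmpty(restrict)) NULL
            else buildSearchString(restrict, backend@exactReaction,
                                   backend@exactIndication)
  out <- fetchCount(backend, apiQuery(search = search, count = countField,
                                      limit = 100L))
  out <- out[order(-out$count, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
})

writeFixture <- function(dir, key, obj) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  index <- readFixtureIndex(dir)
  f <- index[[key]] %||% sprintf("r%04d.json", length(index) + 1L)
  jsonlite::write_json(obj, file.path(dir, f), auto_unbox = TRUE, digits = NA)
  index[[key]] <- f
  jsonlite::write_json(index, file.path(dir, "index.json"), auto_unbox = TRUE)
  invisible(f)
}

#' Record openFDA-style fixture responses from a local store
#'
#' Computes totals (and optionally count aggregations) on a local
#' \linkS4class{ReportStore} and writes them as openFDA-style response
#' documents keyed by their canonical request, so a fixture-backed
#' [remoteStore()] replays them bit-reproducibly. The all-reports total is
#' always recorded. Count lists are capped at 100 terms, as the live
#' service caps them.
#'
#' @param store the local \linkS4class{ReportStore} standing in for the
#'   service's collection.
#' @param dir fixture directory (created if needed).
#' @param queries list of \linkS4class{ReportQuery} objects whose totals
#'   to record.
#' @param countFields character vector of fields (\code{"drug"},
#'   \code{"reaction"}, \code{"indication"}) whose count aggregations to
#'   record, one per query plus unrestricted.
#' @param exactReaction,exactIndication dialect flags, must match the
#'   replaying backend's.
#' @return \code{dir}, invisibly.
#' @export
recordFixtures <- function(store, dir, queries = list(),
                           countFields = character(0),
                           exactReaction = TRUE, exactIndication = TRUE) {
  writeFixture(dir, requestKey(""), list(
    meta = list(results = list(total = length(store)))))
  for (q in queries) {
    search <- buildSearchString(q, exactReaction, exactIndication)
    n <- countReports(store, q)
    obj <- if (n == 0L) list(error = list(code = "NOT_FOUND",
                                          message = "No matches found!"))
           else list(meta = list(results = list(total = n)))
    writeFixture(dir, requestKey(search), obj)
  }
  for (f in countFields) {
    countField <- paste0(FIELD_MAP[[f]], ".exact")
    emit <- function(restrict, search) {
      lt <- listTerms(store, f, restrict)
      lt <- lt[seq_len(min(100L, nrow(lt))), , drop = FALSE]
      results <- lapply(seq_len(nrow(lt)), function(i)
        list(term = lt$term[i], count = lt$count[i]))
      writeFixture(dir, requestKey(search, countField),
                   list(results = results))
    }
    emit(NULL, NULL)
    for (q in queries)
      emit(q, buildSearchString(q, exactReaction, exactIndication))
  }
  invisible(dir)
}
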