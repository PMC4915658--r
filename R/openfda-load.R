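parseReportObject <- function(rep) {
  id <- rep$safetyreportid
  if (is.null(id) || !nzchar(as.character(id)[1])) return(NULL)
  drugs <- character(0); indications <- character(0); uncleaned <- FALSE
  for (entry in rep$patient$drug %||% list()) {
    subst <- unlist(entry$openfda$substance_name, use.names = FALSE)
    if (length(subst)) {
      # one product may map to several substances; all enter the drug set
      drugs <- c(drugs, subst)
    } else if (!is.null(entry$medicinalproduct)) {
      drugs <- c(drugs, as.character(entry$medicinalproduct))
      uncleaned <- TRUE
    }
    if (!is.null(entry$drugindication))
      indications <- c(indications, as.character(entry$drugindication))
  }
  reactions <- unlist(lapply(rep$patient$reaction %||% list(),
                             function(r) r$reactionmeddrapt), use.names = FALSE)
  list(id = as.character(id)[1], drugs = drugs,
       reactions = as.character(reactions %||% character(0)),
       indications = indications, uncleaned = uncleaned)
}

readReportObjects <- function(path) {
  txt <- readLines(path, warn = FALSE)
  isNdjson <- grepl("\\.(ndjson|jsonl)$", path, ignore.case = TRUE)
  if (!isNdjson) {
    doc <- tryCatch(jsonlite::fromJSON(paste(txt, collapse = "\n"),
                                       simplifyVector = FALSE),
                    error = function(e)
                      stop("malformed JSON in ", path, ": ", conditionMessage(e),
                           call. = FALSE))
    if (!is.null(names(doc)) && "results" %in% names(doc)) doc$results
    else if (is.null(names(doc))) doc
    else stop("malformed JSON in ", path,
              ": expected a 'results' array or a bare array of reports",
              call. = FALSE)
  } else {
    lines <- txt[nzchar(trimws(txt))]
    lapply(seq_along(lines), function(i)
      tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
               error = function(e)
                 stop("malformed JSON in ", path, " line ", i, ": ",
                      conditionMessage(e), call. = FALSE)))
  }
}

#' Load safety reports from openFDA drug-event JSON
#'
#' Reads one or more documents in the openFDA \code{/drug/event.json}
#' result schema (an object with a \code{results} array, or a bare array
#' of report objects, or newline-delimited JSON with one report object per
#' line in \code{.ndjson}/\code{.jsonl} files) into an indexed
#' \linkS4class{ReportStore}.
#'
#' Drug terms come from \code{patient.drug.openfda.substance_name}; a drug
#' entry without any cleaned substance name falls back to its verbatim
#' \code{medicinalproduct} and the report is flagged uncleaned. Reactions
#' come from \code{patient.reaction.reactionmeddrapt}, indications from
#' \code{patient.drug.drugindication} (union over the report's drug
#' entries). Reports lacking a \code{safetyreportid} are skipped with a
#' warning; duplicate ids keep the last occurrence with a warning (the
#' service serves versioned reports).
#'
#' @param source path to a JSON/NDJSON file or to a directory whose
#'   \code{.json}/\code{.ndjson}/\code{.jsonl} files are all loaded.
#' @return a \linkS4class{ReportStore}.
#' @export
loadOpenfdaJson <- function(source) {
  files <- if (dir.exists(source)) {
    list.files(source, pattern = "\\.(json|ndjson|jsonl)$", full.names = TRUE,
               ignore.case = TRUE)
  } else {
    if (!file.exists(source)) stop("no such file or directory: ", source)
    source
  }
  objs <- unlist(lapply(files, readReportObjects), recursive = FALSE)
  parsed <- list(); skipped <- 0L
  for (rep in objs) {
    p <- parseReportObject(rep)
    if (is.null(p)) { skipped <- skipped + 1L; next }
    parsed[[length(parsed) + 1L]] <- p
  }
  if (skipped)
    warning(skipped, " report(s) without safetyreportid skipped", call. = FALSE)
  ids <- vapply(parsed, `[[`, character(1), "id")
  dup <- duplicated(ids, fromLast = TRUE)   # last occurrence wins
  if (any(dup)) {
    warning("duplicate safetyreportid(s), keeping last occurrence: ",
            paste(unique(ids[dup]), collapse = ", "), call. = FALSE)
    parsed <- parsed[!dup]; ids <- ids[!dup]
  }
  reportStore(ids,
              drugs = lapply(parsed, `[[`, "drugs"),
              reactions = lapply(parsed, `[[`, "reactions"),
              indications = lapply(parsed, `[[`, "indications"),
              uncleaned = vapply(parsed, `[[`, logical(1), "uncleaned"))
}

#' Write a store as newline-delimited openFDA-style JSON
#'
#' One report object per line, in the same schema [loadOpenfdaJson()]
#' reads, so generated collections round-trip exactly.
#'
#' @param store a \linkS4class{ReportStore}.
#' @param path output file path (conventionally \code{.ndjson}).
#' @return \code{path}, invisibly.
#' @export
writeReportsNdjson <- function(store, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(length(store))) {
    uncleaned <- store@uncleaned[i]
    drugEntries <- lapply(store@drugs[[i]], function(d) {
      if (uncleaned) list(medicinalproduct = d)
      else list(medicinalproduct = d,
                openfda = list(substance_name = I(list(d))))
    })
    # indications ride on dedicated drug-free entries: the loader unions
    # drugindication over all of a report's drug entries
    for (ind in store@indications[[i]])
      drugEntries[[length(drugEntries) + 1L]] <- list(drugindication = ind)
    obj <- list(
      safetyreportid = store@reportId[i],
      patient = list(
        drug = drugEntries,
        reaction = lapply(store@reactions[[i]],
                          function(r) list(reactionmeddrapt = r))))
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE), con)
  }
  invisible(path)
}
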