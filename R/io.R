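#' Flatten an analysis result to a data.frame
#'
#' The canonical tabular rendering used by both the CSV and JSON writers,
#' so the two formats are field-equal row by row. Undefined measures stay
#' \code{NA} here; the writers render them as empty CSV cells and JSON
#' nulls, never as 0.
#'
#' @param x a \linkS4class{DpaResult}, \linkS4class{DrugRanking},
#'   \linkS4class{ProfileComparison}, a [ddiScreen()] table or a
#'   [confounderScreen()] list.
#' @return a data.frame.
#' @export
resultFrame <- function(x) {
  if (is(x, "DpaResult")) {
    cells <- tableCells(x); m <- tableMargins(x)
    df <- data.frame(DE = cells[["DE"]], De = cells[["De"]],
                     dE = cells[["dE"]], de = cells[["de"]],
                     D = m[["D"]], d = m[["d"]], E = m[["E"]], e = m[["e"]],
                     N = m[["N"]], rate = x@rate, ROR = x@ror, PRR = x@prr,
                     RRR = x@rrr, chi2 = x@chi2, signal = x@signal)
  } else if (is(x, "DrugRanking")) {
    df <- x@entries
    df <- cbind(event = rep(x@event, nrow(df)), df)
  } else if (is(x, "ProfileComparison")) {
    df <- x@rows
    df <- cbind(drug1 = rep(x@drug1, nrow(df)),
                drug2 = rep(x@drug2, nrow(df)), df)
  } else if (is.data.frame(x)) {
    df <- x
  } else if (is.list(x) && all(c("coDrugs", "coIndications") %in% names(x))) {
    cd <- x$coDrugs; ci <- x$coIndications
    df <- rbind(
      if (nrow(cd)) cbind(kind = "co-drug", cd) else NULL,
      if (nrow(ci)) cbind(kind = "co-indication", ci) else NULL)
    if (is.null(df)) df <- data.frame(kind = character(0), term = character(0),
                                      count = integer(0), fraction = numeric(0))
  } else stop("no tabular rendering for objects of class ", class(x)[1])
  rownames(df) <- NULL
  df
}

#' Write a result as CSV or JSON
#'
#' CSV output is RFC-4180 style: header row, CRLF line endings, quoted
#' character fields, undefined values as empty cells. JSON output is an
#' array of row objects mirroring the same fields at full precision, with
#' undefined values as nulls. Parsing both back yields field-equal
#' tables in identical row order.
#'
#' @param x a result object accepted by [resultFrame()].
#' @param path output file path, or \code{""} for stdout.
#' @return \code{path}, invisibly.
#' @export
writeResultCsv <- function(x, path = "") {
  df <- resultFrame(x)
  utils::write.table(df, file = path, sep = ",", na = "", row.names = FALSE,
                     qmethod = "double", eol = "\r\n")
  invisible(path)
}

#' @rdname writeResultCsv
#' @export
writeResultJson <- function(x, path = "") {
  df <- resultFrame(x)
  json <- jsonlite::toJSON(df, dataframe = "rows", na = "null", digits = NA)
  if (identical(path, "")) cat(json, "\n") else writeLines(json, path)
  invisible(path)
}
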