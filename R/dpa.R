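#' Construct a 2x2 contingency table from its cells
#'
#' @param DE,De,dE,de non-negative integer report counts (drug/event
#'   presence-absence combinations).
#' @return a \linkS4class{ContingencyTable}.
#' @examples
#' contingencyTable(DE = 2, De = 8, dE = 8, de = 72)
#' @export
contingencyTable <- function(DE, De, dE, de) {
  asCount <- function(x, nm) {
    if (length(x) != 1L || is.na(x) || x < 0 || x != as.integer(x))
      stop(nm, " must be a single non-negative integer count")
    as.integer(x)
  }
  new("ContingencyTable", DE = asCount(DE, "DE"), De = asCount(De, "De"),
      dE = asCount(dE, "dE"), de = asCount(de, "de"))
}

#' Cells and margins of a contingency table
#'
#' @param x a \linkS4class{ContingencyTable} or \linkS4class{DpaResult}.
#' @return \code{tableCells}: named integer vector (DE, De, dE, de);
#'   \code{tableMargins}: named numeric vector (D, d, E, e, N). Margins
#'   always satisfy D + d = E + e = N.
#' @export
#' @name tableCells
setMethod("tableCells", "ContingencyTable", function(x)
  c(DE = x@DE, De = x@De, dE = x@dE, de = x@de))

#' @rdname tableCells
setMethod("tableMargins", "ContingencyTable", function(x) {
  # numeric, not integer: products of margins overflow 32-bit counts
  c(D = x@DE + as.numeric(x@De), d = x@dE + as.numeric(x@de),
    E = x@DE + as.numeric(x@dE), e = x@De + as.numeric(x@de),
    N = x@DE + x@De + x@dE + as.numeric(x@de))
})

setMethod("tableCells", "DpaResult", function(x) tableCells(x@table))
setMethod("tableMargins", "DpaResult", function(x) tableMargins(x@table))

setMethod("show", "ContingencyTable", function(object) {
  m <- tableMargins(object)
  cat("2x2 contingency table (drug x event)\n")
  print(matrix(c(object@DE, object@De, m[["D"]],
                 object@dE, object@de, m[["d"]],
                 m[["E"]], m[["e"]], m[["N"]]), nrow = 3, byrow = TRUE,
               dimnames = list(c("D", "d", "sum"), c("E", "e", "sum"))))
})

#' Build the drug-by-event contingency table from a backend
#'
#' Counts DE = drug AND event, and derives De, dE and de from the D, E and
#' N counts, all within the optional mask (the background-correction
#' subpopulation). Only four backend counts are issued, so the same code
#' path serves local stores and the remote openFDA-dialect backend.
#'
#' @param backend a \linkS4class{ReportStore} or \linkS4class{RemoteBackend}.
#' @param drugQuery a \linkS4class{ReportQuery} using only drug fields
#'   (defines exposure D).
#' @param eventQuery a \linkS4class{ReportQuery} using only reaction fields
#'   (defines event occurrence E).
#' @param mask optional \linkS4class{ReportQuery} restricting the
#'   population first.
#' @return a \linkS4class{ContingencyTable}; cells sum to the masked
#'   population size.
#' @export
buildContingency <- function(backend, drugQuery, eventQuery, mask = NULL) {
  usesOnly <- function(q, fields) {
    others <- setdiff(c("drug", "reaction", "indication"), fields)
    all(vapply(others, function(f)
      length(slot(q, paste0(f, "All"))) + length(slot(q, paste0(f, "None"))) == 0L,
      logical(1)))
  }
  if (!usesOnly(drugQuery, "drug"))
    stop("drugQuery may constrain drug fields only")
  if (!usesOnly(eventQuery, "reaction"))
    stop("eventQuery may constrain reaction fields only")
  N  <- countReports(backend, reportQuery(), mask)
  D  <- countReports(backend, drugQuery, mask)
  E  <- countReports(backend, eventQuery, mask)
  DE <- countReports(backend, queryAnd(drugQuery, eventQuery), mask)
  contingencyTable(DE = DE, De = D - DE, dE = E - DE, de = N - D - E + DE)
}

#' Disproportionality measures on a 2x2 table
#'
#' All measures return \code{NA} (the undefined marker) when their
#' denominator is zero; no continuity correction is applied to the ratios.
#' \describe{
#'   \item{reportingRate}{DE / D — the fraction of the drug's reports that
#'     carry the event. Not interpretable alone; it must be set against
#'     the background rates.}
#'   \item{ror}{reporting odds ratio, DE*de / (dE*De).}
#'   \item{prr}{proportional reporting ratio, DE*d / (dE*D) — the
#'     relative-risk analogue on report counts.}
#'   \item{rrr}{relative reporting ratio, DE*N / (E*D) — observed over
#'     expected count under independence.}
#'   \item{chisqYates}{Yates-corrected chi-squared,
#'     N*(|DE*de - dE*De| - N/2)^2 / (E*e*D*d), with the corrected
#'     difference clamped at 0 when |DE*de - dE*De| < N/2 (standard Yates
#'     practice; set \code{clamp = FALSE} for the unclamped literal
#'     formula). Undefined when any margin is zero.}
#' }
#' A value of 1 for the three ratios means neither disproportional
#' association nor dissociation of drug and event.
#'
#' @param x a \linkS4class{ContingencyTable} (or \linkS4class{DpaResult},
#'   whose stored measures are returned).
#' @param clamp clamp the Yates-corrected difference at zero.
#' @return a numeric scalar, \code{NA} when undefined.
#' @name dpaMeasures
NULL

#' @rdname dpaMeasures
setMethod("reportingRate", "ContingencyTable", function(x) {
  D <- x@DE + x@De
  if (D == 0) NA_real_ else x@DE / D
})

#' @rdname dpaMeasures
setMethod("ror", "ContingencyTable", function(x) {
  den <- as.numeric(x@dE) * x@De
  if (den == 0) NA_real_ else (as.numeric(x@DE) * x@de) / den
})

#' @rdname dpaMeasures
setMethod("prr", "ContingencyTable", function(x) {
  d <- as.numeric(x@dE) + x@de
  D <- as.numeric(x@DE) + x@De
  if (x@dE * D == 0) NA_real_ else (x@DE * d) / (x@dE * D)
})

#' @rdname dpaMeasures
setMethod("rrr", "ContingencyTable", function(x) {
  m <- tableMargins(x)
  if (m[["E"]] * m[["D"]] == 0) NA_real_
  else (x@DE * m[["N"]]) / (m[["E"]] * m[["D"]])
})

#' @rdname dpaMeasures
setMethod("chisqYates", "ContingencyTable", function(x, clamp = TRUE) {
  m <- tableMargins(x)
  if (m[["E"]] == 0 || m[["e"]] == 0 || m[["D"]] == 0 || m[["d"]] == 0)
    return(NA_real_)
  N <- m[["N"]]
  diff <- abs(as.numeric(x@DE) * x@de - as.numeric(x@dE) * x@De) - N / 2
  if (clamp) diff <- max(diff, 0)
  N * diff^2 / (m[["E"]] * m[["e"]] * m[["D"]] * m[["d"]])
})

#' Evans signal criteria
#'
#' The conventional minimal criteria for a signal of disproportionality:
#' PRR > 2, Yates chi-squared > 4 (about p < 0.05) and DE > 3, all strict
#' inequalities. Thresholds are configurable; the flag is \code{NA} when
#' PRR or chi-squared is undefined for the table.
#'
#' @param x a \linkS4class{ContingencyTable} or \linkS4class{DpaResult}.
#' @param prrMin,chi2Min,deMin signal thresholds (defaults 2, 4, 3).
#' @return logical scalar or \code{NA}.
#' @name evansSignal
NULL

#' @rdname evansSignal
setMethod("evansSignal", "ContingencyTable",
          function(x, prrMin = 2, chi2Min = 4, deMin = 3) {
  p <- prr(x); chi <- chisqYates(x)
  if (is.na(p) || is.na(chi)) return(NA)
  p > prrMin && chi > chi2Min && x@DE > deMin
})

#' Full disproportionality analysis of one drug-event pair
#'
#' Builds the contingency table and bundles all measures plus the Evans
#' signal flag. Pure: the same backend and queries always give an
#' identical result.
#'
#' @inheritParams buildContingency
#' @param drug,event either bare terms (coerced to single-term queries) or
#'   \linkS4class{ReportQuery} objects.
#' @param prrMin,chi2Min,deMin Evans thresholds, see [evansSignal()].
#' @return a \linkS4class{DpaResult}.
#' @examples
#' st <- fixtureModelCase(2)
#' analyzePair(st, "DRUG_X", "EVENT_Y")
#' @export
analyzePair <- function(backend, drug, event, mask = NULL,
                        prrMin = 2, chi2Min = 4, deMin = 3) {
  drugQuery <- if (is(drug, "ReportQuery")) drug else reportQuery(drugAll = drug)
  eventQuery <- if (is(event, "ReportQuery")) event
                else reportQuery(reactionAll = event)
  tab <- buildContingency(backend, drugQuery, eventQuery, mask)
  new("DpaResult", table = tab,
      rate = reportingRate(tab), ror = ror(tab), prr = prr(tab),
      rrr = rrr(tab), chi2 = chisqYates(tab),
      signal = evansSignal(tab, prrMin, chi2Min, deMin),
      thresholds = c(prrMin = prrMin, chi2Min = chi2Min, deMin = deMin))
}

#' Extract the measures of a DpaResult
#'
#' @param x a \linkS4class{DpaResult}.
#' @return named numeric vector (rate, ROR, PRR, RRR, chi2).
#' @export
dpaMeasures <- function(x) {
  stopifnot(is(x, "DpaResult"))
  c(rate = x@rate, ROR = x@ror, PRR = x@prr, RRR = x@rrr, chi2 = x@chi2)
}

#' @rdname dpaMeasures
#' @export
isSignal <- function(x) { stopifnot(is(x, "DpaResult")); x@signal }

#' @rdname dpaMeasures
#' @export
dpaTable <- function(x) { stopifnot(is(x, "DpaResult")); x@table }

setMethod("reportingRate", "DpaResult", function(x) x@rate)
setMethod("ror", "DpaResult", function(x) x@ror)
setMethod("prr", "DpaResult", function(x) x@prr)
setMethod("rrr", "DpaResult", function(x) x@rrr)
setMethod("chisqYates", "DpaResult", function(x, clamp = TRUE) x@chi2)
setMethod("evansSignal", "DpaResult",
          function(x, prrMin = 2, chi2Min = 4, deMin = 3) x@signal)

setMethod("show", "DpaResult", function(object) {
  show(object@table)
  fmt <- function(v) ifelse(is.na(v), "undefined", signif(v, 4))
  cat(sprintf("rate = %s  ROR = %s  PRR = %s  RRR = %s  chi2(Yates) = %s\n",
              fmt(object@rate), fmt(object@ror), fmt(object@prr),
              fmt(object@rrr), fmt(object@chi2)))
  cat("Evans signal:",
      if (is.na(object@signal)) "undefined" else object@signal, "\n")
})
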