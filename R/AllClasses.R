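#' ReportQuery: a conjunctive boolean query over safety reports
#'
#' A report matches when every term in each \code{*All} slot is present in
#' the corresponding field and every term in each \code{*None} slot is
#' absent. A query with all six slots empty matches every report. A term
#' appearing in both the \code{All} and \code{None} slot of the same field
#' is contradictory and rejected at construction.
#'
#' @slot drugAll,drugNone character vectors of normalized substance names.
#' @slot reactionAll,reactionNone character vectors of MedDRA preferred
#'   terms (reactions).
#' @slot indicationAll,indicationNone character vectors of MedDRA preferred
#'   terms (indications).
#' @seealso [reportQuery()]
#' @export
setClass("ReportQuery", representation(
  drugAll = "character", drugNone = "character",
  reactionAll = "character", reactionNone = "character",
  indicationAll = "character", indicationNone = "character"
), prototype(
  drugAll = character(0), drugNone = character(0),
  reactionAll = character(0), reactionNone = character(0),
  indicationAll = character(0), indicationNone = character(0)
))

setValidity("ReportQuery", function(object) {
  msgs <- character(0)
  for (f in c("drug", "reaction", "indication")) {
    a <- slot(object, paste0(f, "All"))
    n <- slot(object, paste0(f, "None"))
    bad <- intersect(a, n)
    if (length(bad))
      msgs <- c(msgs, sprintf(
        "%s terms both required and excluded: %s", f, paste(bad, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' ReportStore: an indexed in-memory collection of safety reports
#'
#' Each report carries an opaque identifier and three term sets: drugs
#' (normalized substance names), reactions and indications (MedDRA
#' preferred terms). Inverted indexes map each term to the integer
#' positions of the reports containing it, so conjunctive counting is a
#' set-intersection, not a scan. Reports with an empty drug set remain in
#' the store and count toward the complementary cells (the source data
#' contain reports without any cleaned drugname); [dropUndrugged()]
#' derives a store with the opposite policy.
#'
#' @slot reportId character vector of unique report identifiers.
#' @slot drugs,reactions,indications lists of character vectors, parallel
#'   to \code{reportId}.
#' @slot uncleaned logical vector: drug names fell back to the verbatim
#'   \code{medicinalproduct} because no cleaned \code{substance_name} was
#'   available.
#' @slot index environment holding the three inverted indexes.
#' @seealso [reportStore()], [loadOpenfdaJson()]
#' @export
setClass("ReportStore", representation(
  reportId = "character",
  drugs = "list", reactions = "list", indications = "list",
  uncleaned = "logical",
  index = "environment"
))

setValidity("ReportStore", function(object) {
  n <- length(object@reportId)
  if (anyDuplicated(object@reportId)) return("duplicate report ids")
  if (any(!nzchar(object@reportId))) return("empty report id")
  if (length(object@drugs) != n || length(object@reactions) != n ||
      length(object@indications) != n || length(object@uncleaned) != n)
    return("field lists must be parallel to reportId")
  TRUE
})

#' ContingencyTable: the 2x2 drug-by-event table
#'
#' Cells follow the D/E naming convention: upper-case letters for presence
#' (D drug used, E event occurred), lower-case for absence, and
#' juxtaposition for intersection — DE is the count of reports where both
#' the drug was used and the event occurred. Margins D = DE + De,
#' d = dE + de, E = DE + dE, e = De + de and the grand total
#' N = DE + De + dE + de are derived, never stored.
#'
#' @slot DE,De,dE,de non-negative integer report counts.
#' @seealso [contingencyTable()], [buildContingency()]
#' @export
setClass("ContingencyTable", representation(
  DE = "integer", De = "integer", dE = "integer", de = "integer"
))

setValidity("ContingencyTable", function(object) {
  v <- c(object@DE, object@De, object@dE, object@de)
  if (length(v) != 4L || anyNA(v)) return("all four cells must be single integers")
  if (any(v < 0L)) return("cells must be non-negative")
  TRUE
})

#' DpaResult: disproportionality measures for one drug-event pair
#'
#' Bundles the 2x2 table with the reporting rate, ROR, PRR, RRR, the
#' Yates-corrected chi-squared statistic and the Evans signal flag.
#' Measures that are undefined for the table (zero denominators) are
#' \code{NA}; undefinedness propagates into the signal flag.
#'
#' @slot table the underlying \linkS4class{ContingencyTable}.
#' @slot rate,ror,prr,rrr,chi2 numeric scalars, \code{NA} when undefined.
#' @slot signal logical, \code{NA} when PRR or chi-squared is undefined.
#' @slot thresholds named numeric vector (prrMin, chi2Min, deMin) the
#'   signal flag was evaluated against.
#' @seealso [analyzePair()]
#' @export
setClass("DpaResult", representation(
  table = "ContingencyTable",
  rate = "numeric", ror = "numeric", prr = "numeric", rrr = "numeric",
  chi2 = "numeric", signal = "logical", thresholds = "numeric"
))

#' DrugRanking: medication list ranked against one adverse event
#'
#' One row per requested drug with its DE, D, reporting rate and RRR,
#' ordered by RRR descending (the drug most disproportionally associated
#' with the event first — the candidate to discontinue first), ties broken
#' by rate descending then term ascending; rows with undefined RRR sort
#' last.
#'
#' @slot event the reaction term the list was ranked against.
#' @slot entries data.frame with columns drug, DE, D, rate, RRR.
#' @seealso [rankDrugsForEvent()]
#' @export
setClass("DrugRanking", representation(event = "character", entries = "data.frame"))

#' ProfileComparison: pairwise safety-profile comparison
#'
#' Per adverse event reported with either drug (combination excluded), the
#' single-drug counts, rates and RRRs plus the percentage difference of
#' the RRRs relative to their mean. \code{rows} holds the selected rows;
#' \code{allRows} everything before cutoff selection.
#'
#' @slot drug1,drug2 the compared substance names.
#' @slot rows,allRows data.frames with columns event, DE1, DE2, rate1,
#'   rate2, RRR1, RRR2, percDiff.
#' @slot d1Total,d2Total,comboTotal report counts after combination
#'   exclusion (and the combination itself).
#' @slot truncated logical: a backend count list was truncated, the event
#'   universe may be incomplete.
#' @seealso [compareDrugProfiles()]
#' @export
setClass("ProfileComparison", representation(
  drug1 = "character", drug2 = "character",
  rows = "data.frame", allRows = "data.frame",
  d1Total = "integer", d2Total = "integer", comboTotal = "integer",
  truncated = "logical"
))

#' RemoteBackend: openFDA-dialect counting backend
#'
#' Satisfies the [countReports()] / [listTerms()] contract of
#' \linkS4class{ReportStore} by translating queries into openFDA search
#' strings and reading totals and count lists either from a recorded
#' fixture directory (bit-reproducible, used by all tests) or from a live
#' HTTP endpoint.
#'
#' @slot endpoint base URL of a live service ("" when fixture-only).
#' @slot fixtureDir directory of recorded responses ("" when live-only).
#' @slot apiKey optional API key appended to live requests.
#' @slot exactReaction,exactIndication use the \code{.exact} field variants
#'   for reaction / indication terms.
#' @seealso [remoteStore()]
#' @export
setClass("RemoteBackend", representation(
  endpoint = "character", fixtureDir = "character", apiKey = "character",
  exactReaction = "logical", exactIndication = "logical"
))

#' SyntheticConfig: generative model for synthetic report collections
#'
#' Every drug and indication enters a report independently with its
#' marginal probability; each event occurs with its baseline probability
#' multiplied by the risk multipliers of the planted associations whose
#' drug is present, and by the combination multiplier of any planted
#' interaction whose drug pair is fully present. Confounders shift a
#' drug's probability and an event's probability when the indication is
#' present, inducing confounding-by-indication. Effective probabilities
#' are clamped to [0, 1].
#'
#' @slot nReports number of reports to generate.
#' @slot drugVocab,eventVocab,indicationVocab named numeric vectors
#'   (term -> marginal/baseline probability).
#' @slot associations data.frame(drug, event, rho) risk multipliers.
#' @slot confounders data.frame(indication, drug, event, drugMult,
#'   eventMult).
#' @slot interactions data.frame(drug1, drug2, event, comboMult).
#' @slot seed integer RNG seed; identical config + seed gives a
#'   byte-identical collection.
#' @seealso [syntheticConfig()], [generateReports()]
#' @export
setClass("SyntheticConfig", representation(
  nReports = "integer",
  drugVocab = "numeric", eventVocab = "numeric", indicationVocab = "numeric",
  associations = "data.frame", confounders = "data.frame",
  interactions = "data.frame", seed = "integer"
))

setValidity("SyntheticConfig", function(object) {
  probs <- c(object@drugVocab, object@eventVocab, object@indicationVocab)
  if (length(probs) && (anyNA(probs) || any(probs < 0) || any(probs > 1)))
    return("all vocabulary probabilities must lie in [0, 1]")
  if (object@nReports < 0L) return("nReports must be non-negative")
  if (length(object@associations) && any(object@associations$rho < 0))
    return("risk multipliers must be >= 0")
  TRUE
})
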