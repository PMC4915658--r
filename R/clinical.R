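#' Percentage difference of two RRRs relative to their mean
#'
#' Absolute RRR differences mislead: a difference of 1 between RRRs 1 and
#' 2 is meaningful while the same difference between 100 and 101 is
#' probably chance. The percentage difference (RRR1 - RRR2) / mean(RRR1,
#' RRR2) * 100 is bounded in [-200, 200] and antisymmetric in its
#' arguments. When exactly one RRR is 0 the formula's limit (+/-200) is
#' returned; when both are 0 or either is \code{NA} the result is
#' \code{NA}.
#'
#' @param rrr1,rrr2 non-negative numeric vectors (recycled).
#' @return numeric vector of percentage differences.
#' @examples
#' rrrPercDiff(1, 2)     # -66.67: a meaningful difference
#' rrrPercDiff(100, 101) # -0.995: probably chance
#' @export
rrrPercDiff <- function(rrr1, rrr2) {
  n <- max(length(rrr1), length(rrr2))
  rrr1 <- rep_len(rrr1, n); rrr2 <- rep_len(rrr2, n)
  out <- rep(NA_real_, n)
  ok <- !is.na(rrr1) & !is.na(rrr2) & (rrr1 + rrr2) > 0
  out[ok] <- (rrr1[ok] - rrr2[ok]) / ((rrr1[ok] + rrr2[ok]) / 2) * 100
  out
}

#' Algorithm: which drug of a medication list to discontinue first?
#'
#' For a newly observed adverse event and a list of drugs, extracts DE and
#' D per drug (plus E and N once) and computes the reporting rate and RRR
#' of each drug against the event. The drug with the highest RRR is the
#' one most disproportionally associated with the event and the candidate
#' to consider stopping first.
#'
#' @param backend a \linkS4class{ReportStore} or \linkS4class{RemoteBackend}.
#' @param drugs character vector of at least one substance name.
#' @param event a reaction preferred term.
#' @param mask optional \linkS4class{ReportQuery} (background correction).
#' @return a \linkS4class{DrugRanking}; entries sorted by RRR descending,
#'   ties by rate descending then drug ascending, undefined RRRs last.
#' @export
rankDrugsForEvent <- function(backend, drugs, event, mask = NULL) {
  drugs <- normalizeTerms(drugs)
  if (!length(drugs)) stop("at least one drug is required")
  event <- normalizeTerms(event)
  if (length(event) != 1L) stop("exactly one event term is required")
  eventQuery <- reportQuery(reactionAll = event)
  rows <- lapply(drugs, function(d) {
    tab <- buildContingency(backend, reportQuery(drugAll = d), eventQuery, mask)
    m <- tableMargins(tab)
    data.frame(drug = d, DE = tab@DE, D = as.integer(m[["D"]]),
               rate = reportingRate(tab), RRR = rrr(tab))
  })
  entries <- do.call(rbind, rows)
  ord <- order(is.na(entries$RRR), -ifelse(is.na(entries$RRR), -Inf, entries$RRR),
               -ifelse(is.na(entries$rate), -Inf, entries$rate), entries$drug)
  entries <- entries[ord, , drop = FALSE]
  rownames(entries) <- NULL
  new("DrugRanking", event = event, entries = entries)
}

#' @rdname rankDrugsForEvent
#' @param x a \linkS4class{DrugRanking}.
#' @return \code{rankingEntries}: the data.frame of ranked entries.
#' @export
rankingEntries <- function(x) { stopifnot(is(x, "DrugRanking")); x@entries }

setMethod("show", "DrugRanking", function(object) {
  cat(sprintf("Drug ranking for adverse event '%s' (highest RRR first)\n",
              object@event))
  print(object@entries)
})

# counts per reaction term within a restriction, optionally truncated to
# the top `truncateCounts` terms (emulating the openFDA count cap)
restrictedEventCounts <- function(backend, restrict, truncateCounts) {
  lt <- listTerms(backend, "reaction", restrict)
  truncated <- isTRUE(attr(lt, "truncated"))
  if (is.finite(truncateCounts) && nrow(lt) > truncateCounts) {
    lt <- lt[seq_len(truncateCounts), , drop = FALSE]
    truncated <- TRUE
  }
  counts <- lt$count
  names(counts) <- lt$term
  list(counts = counts, truncated = truncated)
}

lookupCount <- function(counts, term) {
  v <- counts[term]
  ifelse(is.na(v), 0L, v)
}

#' Algorithm: pairwise comparison of two drugs' safety profiles
#'
#' The combination population (reports carrying both drugs) is excluded
#' from both single-drug populations, so only cases with either drug but
#' not their combination are considered — for the event-level counts too.
#' For every adverse event reported with either drug, the single-drug
#' RRRs (against the masked store's E and N) and their percentage
#' difference [rrrPercDiff()] are computed. A large percentage difference
#' marks an event predominantly associated with one of the two drugs.
#'
#' @inheritParams rankDrugsForEvent
#' @param drug1,drug2 distinct substance names.
#' @param minDE drop events with DE1 + DE2 below this count (default 0;
#'   the openFDA-backed original effectively applies a records cut-off).
#' @param cutoffLo,cutoffHi selection cut-offs in percent (defaults -75 /
#'   +75; there is no consensus on clinically significant cut-offs, and
#'   asymmetric choices are legitimate).
#' @param allRows return every row regardless of cut-offs in the
#'   \code{rows} slot as well.
#' @param truncateCounts cap each backend count list at this many terms
#'   (default \code{Inf}; set 100 to emulate the openFDA count cap and
#'   its missed-signal behaviour).
#' @return a \linkS4class{ProfileComparison}; rows ordered by event term.
#' @export
compareDrugProfiles <- function(backend, drug1, drug2, mask = NULL,
                                minDE = 0L, cutoffLo = -75, cutoffHi = 75,
                                allRows = FALSE, truncateCounts = Inf) {
  drug1 <- normalizeTerms(drug1); drug2 <- normalizeTerms(drug2)
  if (length(drug1) != 1L || length(drug2) != 1L)
    stop("drug1 and drug2 must be single terms")
  if (identical(drug1, drug2)) stop("drug1 and drug2 must differ")
  q1 <- queryAnd(reportQuery(drugAll = drug1, drugNone = drug2), mask)
  q2 <- queryAnd(reportQuery(drugAll = drug2, drugNone = drug1), mask)
  combo <- queryAnd(reportQuery(drugAll = c(drug1, drug2)), mask)
  N <- countReports(backend, reportQuery(), mask)
  D1 <- countReports(backend, q1)
  D2 <- countReports(backend, q2)
  comboTotal <- countReports(backend, combo)
  e1 <- restrictedEventCounts(backend, q1, truncateCounts)
  e2 <- restrictedEventCounts(backend, q2, truncateCounts)
  eAll <- restrictedEventCounts(backend, mask %||% reportQuery(), Inf)
  events <- sort(union(names(e1$counts), names(e2$counts)))
  truncated <- e1$truncated || e2$truncated
  if (truncated)
    vigilLog("event count list truncated; the event universe is incomplete",
             level = "warn")
  DE1 <- unname(lookupCount(e1$counts, events))
  DE2 <- unname(lookupCount(e2$counts, events))
  E <- unname(lookupCount(eAll$counts, events))
  rrrOf <- function(DE, D) ifelse(E > 0 & D > 0, DE * N / (E * D), NA_real_)
  rows <- data.frame(
    event = events, DE1 = DE1, DE2 = DE2,
    rate1 = if (D1 > 0) DE1 / D1 else NA_real_,
    rate2 = if (D2 > 0) DE2 / D2 else NA_real_,
    RRR1 = rrrOf(DE1, D1), RRR2 = rrrOf(DE2, D2))
  rows$percDiff <- rrrPercDiff(rows$RRR1, rows$RRR2)
  rows <- rows[DE1 + DE2 >= minDE, , drop = FALSE]
  sel <- if (allRows) rep(TRUE, nrow(rows))
         else !is.na(rows$percDiff) &
              (rows$percDiff <= cutoffLo | rows$percDiff >= cutoffHi)
  selected <- rows[sel, , drop = FALSE]
  rownames(rows) <- rownames(selected) <- NULL
  new("ProfileComparison", drug1 = drug1, drug2 = drug2,
      rows = selected, allRows = rows,
      d1Total = as.integer(D1), d2Total = as.integer(D2),
      comboTotal = as.integer(comboTotal), truncated = truncated)
}

#' @rdname compareDrugProfiles
#' @param x a \linkS4class{ProfileComparison}.
#' @param all return the unselected full row set.
#' @export
comparisonRows <- function(x, all = FALSE) {
  stopifnot(is(x, "ProfileComparison"))
  if (all) x@allRows else x@rows
}

setMethod("show", "ProfileComparison", function(object) {
  cat(sprintf("Safety-profile comparison %s vs %s (combination excluded)\n",
              object@drug1, object@drug2))
  cat(sprintf("  D1 = %d, D2 = %d, combination = %d%s\n", object@d1Total,
              object@d2Total, object@comboTotal,
              if (object@truncated) " [count lists truncated]" else ""))
  print(utils::head(object@rows, 20))
  if (nrow(object@rows) > 20) cat("  ...", nrow(object@rows), "rows\n")
})

#' Algorithm: drug-drug interaction screen
#'
#' Contrasts both drugs alone against their combination: per adverse
#' event, the expected rate under additivity is the sum of the single-drug
#' reporting rates (each on its combination-excluded population) and
#' \code{rateDiff = expected - observed combination rate}. A negative
#' rateDiff (observed exceeds expected) suggests synergy, a positive one
#' antagonism.
#'
#' @inheritParams compareDrugProfiles
#' @param cutoffLo,cutoffHi selection cut-offs on the rate-difference
#'   scale (defaults -0.03 / +0.035); rows with \code{rateDiff <=
#'   cutoffLo} or \code{>= cutoffHi} are kept.
#' @return data.frame with columns event, rateD1, rateD2, rateCombo,
#'   expected, rateDiff, sorted by |rateDiff| descending; attributes
#'   \code{drug1}, \code{drug2}, \code{comboTotal}, \code{flagged} (TRUE
#'   when no combination reports exist, leaving every combination rate
#'   undefined) and \code{allRows} (the unselected table).
#' @export
ddiScreen <- function(backend, drug1, drug2, mask = NULL, minDE = 0L,
                      cutoffLo = -0.03, cutoffHi = 0.035,
                      allRows = FALSE, truncateCounts = Inf) {
  drug1 <- normalizeTerms(drug1); drug2 <- normalizeTerms(drug2)
  if (length(drug1) != 1L || length(drug2) != 1L)
    stop("drug1 and drug2 must be single terms")
  if (identical(drug1, drug2)) stop("drug1 and drug2 must differ")
  q1 <- queryAnd(reportQuery(drugAll = drug1, drugNone = drug2), mask)
  q2 <- queryAnd(reportQuery(drugAll = drug2, drugNone = drug1), mask)
  qc <- queryAnd(reportQuery(drugAll = c(drug1, drug2)), mask)
  D1 <- countReports(backend, q1)
  D2 <- countReports(backend, q2)
  Dc <- countReports(backend, qc)
  e1 <- restrictedEventCounts(backend, q1, truncateCounts)
  e2 <- restrictedEventCounts(backend, q2, truncateCounts)
  ec <- restrictedEventCounts(backend, qc, truncateCounts)
  events <- sort(Reduce(union, list(names(e1$counts), names(e2$counts),
                                    names(ec$counts))))
  DE1 <- unname(lookupCount(e1$counts, events))
  DE2 <- unname(lookupCount(e2$counts, events))
  DEc <- unname(lookupCount(ec$counts, events))
  flagged <- Dc == 0L
  if (flagged)
    vigilLog("no combination reports: all combination rates undefined",
             level = "warn")
  rows <- data.frame(
    event = events,
    rateD1 = if (D1 > 0) DE1 / D1 else NA_real_,
    rateD2 = if (D2 > 0) DE2 / D2 else NA_real_,
    rateCombo = if (Dc > 0) DEc / Dc else NA_real_)
  rows$expected <- rows$rateD1 + rows$rateD2
  rows$rateDiff <- rows$expected - rows$rateCombo
  rows <- rows[DE1 + DE2 + DEc >= minDE, , drop = FALSE]
  rows <- rows[order(-abs(ifelse(is.na(rows$rateDiff), -Inf, rows$rateDiff)),
                     rows$event), , drop = FALSE]
  rownames(rows) <- NULL
  sel <- if (allRows || flagged) rep(TRUE, nrow(rows))
         else !is.na(rows$rateDiff) &
              (rows$rateDiff <= cutoffLo | rows$rateDiff >= cutoffHi)
  out <- rows[sel, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "drug1") <- drug1; attr(out, "drug2") <- drug2
  attr(out, "comboTotal") <- as.integer(Dc)
  attr(out, "flagged") <- flagged
  attr(out, "allRows") <- rows
  out
}

#' Run an analysis background-corrected by indication
#'
#' Background correction (PRR-by-therapeutic-area) restricts every count —
#' N, E, D, DE — to the subpopulation of reports carrying a given
#' indication, removing confounding by the treated disease. Equivalent to
#' passing \code{mask = reportQuery(indicationAll = indication)} to the
#' wrapped analysis.
#'
#' @param backend a \linkS4class{ReportStore} or \linkS4class{RemoteBackend}.
#' @param fun an analysis function taking \code{(backend, ..., mask = )},
#'   e.g. [analyzePair()], [rankDrugsForEvent()], [compareDrugProfiles()].
#' @param indication an indication preferred term, or a full
#'   \linkS4class{ReportQuery} mask.
#' @param ... passed through to \code{fun}.
#' @return whatever \code{fun} returns, computed within the mask.
#' @export
backgroundCorrected <- function(backend, fun, indication, ...) {
  mask <- if (is(indication, "ReportQuery")) indication
          else reportQuery(indicationAll = indication)
  if (countReports(backend, mask) == 0L)
    warning("background mask matches no reports; all measures will be undefined",
            call. = FALSE)
  fun(backend, ..., mask = mask)
}

#' Screen the DE subpopulation for confounders
#'
#' Any signal might be due to a confounding factor: looking at the drugs
#' and indications reported concomitantly within the DE subpopulation
#' (reports carrying both the index drug and the event) reveals
#' candidates — e.g. co-prescribed cytotoxics behind a
#' steroid-thrombocytopenia signal. Candidates found here are what
#' background correction can then mask out.
#'
#' @param store a \linkS4class{ReportStore} (or remote backend supporting
#'   restricted term listing).
#' @param drug,event the index drug-event pair.
#' @param topK maximum number of co-terms per list (>= 1).
#' @return list with data.frames \code{coDrugs} and \code{coIndications}
#'   (columns term, count, fraction — fraction of the DE subpopulation),
#'   the subpopulation size \code{nDE}, and \code{flagged} = TRUE when the
#'   DE subpopulation is empty.
#' @export
confounderScreen <- function(store, drug, event, topK = 10L) {
  if (topK < 1L) stop("topK must be >= 1")
  drug <- normalizeTerms(drug); event <- normalizeTerms(event)
  sub <- reportQuery(drugAll = drug, reactionAll = event)
  nDE <- countReports(store, sub)
  emptyDf <- data.frame(term = character(0), count = integer(0),
                        fraction = numeric(0))
  if (nDE == 0L)
    return(list(coDrugs = emptyDf, coIndications = emptyDf, nDE = 0L,
                flagged = TRUE))
  top <- function(field, excludeTerms = character(0)) {
    lt <- listTerms(store, field, restrict = sub)
    lt <- lt[!lt$term %in% excludeTerms, , drop = FALSE]
    lt <- lt[seq_len(min(topK, nrow(lt))), , drop = FALSE]
    lt$fraction <- lt$count / nDE
    rownames(lt) <- NULL
    lt
  }
  list(coDrugs = top("drug", excludeTerms = drug),
       coIndications = top("indication"), nDE = nDE, flagged = FALSE)
}
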