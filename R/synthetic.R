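emptyAssoc <- function() data.frame(drug = character(0), event = character(0),
                                    rho = numeric(0))
emptyConf <- function() data.frame(indication = character(0),
                                   drug = character(0), event = character(0),
                                   drugMult = numeric(0), eventMult = numeric(0))
emptyInter <- function() data.frame(drug1 = character(0), drug2 = character(0),
                                    event = character(0), comboMult = numeric(0))

#' Configure a synthetic report collection
#'
#' The generative model: every drug and indication enters each report
#' independently with its marginal probability; each event occurs with
#' its baseline probability multiplied by the risk multiplier rho of
#' every planted association whose drug is present, by the event
#' multiplier of every confounder whose indication is present, and by the
#' combination multiplier of every interaction whose drug pair is fully
#' present; effective probabilities are clamped to [0, 1]. Confounder
#' indications also multiply their drug's probability, inducing
#' confounding-by-indication. Under this model, for a planted (drug,
#' event, rho) the expected RRR is rho / (1 + pD * (rho - 1)) where pD is
#' the drug's marginal — close to rho while the drug is rare.
#'
#' Defaults emulate a modest spontaneous-report collection: a handful of
#' drugs each on about 2 percent of reports and events with baselines of
#' 1 to 5 percent, the scale at which signal-detection practice operates.
#'
#' @param nReports number of reports.
#' @param drugVocab,eventVocab,indicationVocab named numeric vectors, term
#'   to probability.
#' @param associations data.frame(drug, event, rho).
#' @param confounders data.frame(indication, drug, event, drugMult,
#'   eventMult).
#' @param interactions data.frame(drug1, drug2, event, comboMult).
#' @param seed integer RNG seed; identical config + seed gives an
#'   identical collection.
#' @return a \linkS4class{SyntheticConfig}.
#' @export
syntheticConfig <- function(nReports = 10000L,
                            drugVocab = stats::setNames(rep(0.02, 6),
                              paste0("DRUG_", LETTERS[1:6])),
                            eventVocab = stats::setNames(
                              c(0.01, 0.02, 0.03, 0.04, 0.05, 0.02),
                              paste0("EVENT_", c("Y", "R", "S", "T", "U", "V"))),
                            indicationVocab = stats::setNames(rep(0.05, 3),
                              c("HYPERTENSION", "DEPRESSION", "PAIN")),
                            associations = emptyAssoc(),
                            confounders = emptyConf(),
                            interactions = emptyInter(),
                            seed = 1L) {
  normVocab <- function(v) {
    names(v) <- toupper(trimws(names(v)))
    v
  }
  new("SyntheticConfig", nReports = as.integer(nReports),
      drugVocab = normVocab(drugVocab), eventVocab = normVocab(eventVocab),
      indicationVocab = normVocab(indicationVocab),
      associations = associations, confounders = confounders,
      interactions = interactions, seed = as.integer(seed))
}

membershipToList <- function(mat, n) {
  out <- replicate(n, character(0), simplify = FALSE)
  if (is.null(mat) || !ncol(mat)) return(out)
  hits <- which(mat, arr.ind = TRUE)
  if (nrow(hits)) {
    sp <- split(colnames(mat)[hits[, 2]], hits[, 1])
    out[as.integer(names(sp))] <- lapply(sp, sort)
  }
  out
}

#' Generate a synthetic report store
#'
#' @param config a \linkS4class{SyntheticConfig}; see [syntheticConfig()]
#'   for the generative model.
#' @return a \linkS4class{ReportStore} with sequential report ids.
#' @examples
#' cfg <- syntheticConfig(nReports = 1000,
#'   associations = data.frame(drug = "DRUG_A", event = "EVENT_Y", rho = 5))
#' generateReports(cfg)
#' @export
generateReports <- function(config) {
  validObject(config)
  n <- config@nReports
  if (exists(".Random.seed", envir = globalenv())) {
    oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
  }
  set.seed(config@seed)
  draw <- function(p) stats::runif(n) < p
  indMat <- if (length(config@indicationVocab))
    vapply(config@indicationVocab, draw, logical(n)) else NULL
  if (n == 1L && !is.null(indMat)) indMat <- matrix(indMat, nrow = 1,
    dimnames = list(NULL, names(config@indicationVocab)))
  drugMat <- NULL
  if (length(config@drugVocab)) {
    drugMat <- matrix(FALSE, n, length(config@drugVocab),
                      dimnames = list(NULL, names(config@drugVocab)))
    for (d in names(config@drugVocab)) {
      p <- rep(config@drugVocab[[d]], n)
      cf <- config@confounders[config@confounders$drug == d, , drop = FALSE]
      for (i in seq_len(nrow(cf)))
        p <- p * ifelse(indMat[, cf$indication[i]], cf$drugMult[i], 1)
      drugMat[, d] <- draw(pmin(pmax(p, 0), 1))
    }
  }
  evMat <- NULL
  if (length(config@eventVocab)) {
    evMat <- matrix(FALSE, n, length(config@eventVocab),
                    dimnames = list(NULL, names(config@eventVocab)))
    for (e in names(config@eventVocab)) {
      p <- rep(config@eventVocab[[e]], n)
      as <- config@associations[config@associations$event == e, , drop = FALSE]
      for (i in seq_len(nrow(as)))
        p <- p * ifelse(drugMat[, as$drug[i]], as$rho[i], 1)
      cf <- config@confounders[config@confounders$event == e, , drop = FALSE]
      for (i in seq_len(nrow(cf)))
        p <- p * ifelse(indMat[, cf$indication[i]], cf$eventMult[i], 1)
      ia <- config@interactions[config@interactions$event == e, , drop = FALSE]
      for (i in seq_len(nrow(ia)))
        p <- p * ifelse(drugMat[, ia$drug1[i]] & drugMat[, ia$drug2[i]],
                        ia$comboMult[i], 1)
      evMat[, e] <- draw(pmin(pmax(p, 0), 1))
    }
  }
  reportStore(sprintf("SYN%07d", seq_len(n)),
              drugs = membershipToList(drugMat, n),
              reactions = membershipToList(evMat, n),
              indications = membershipToList(indMat, n))
}

# raw field lists for a block of reports realizing exact 2x2 cells
cellBlock <- function(DE, De, dE, de, drug, event, indication = NULL,
                      idPrefix = "R") {
  n <- DE + De + dE + de
  hasDrug <- c(rep(TRUE, DE + De), rep(FALSE, dE + de))
  hasEvent <- c(rep(TRUE, DE), rep(FALSE, De), rep(TRUE, dE), rep(FALSE, de))
  list(
    ids = sprintf("%s%05d", idPrefix, seq_len(n)),
    drugs = lapply(hasDrug, function(h) if (h) drug else "DRUG_OTHER"),
    reactions = lapply(hasEvent, function(h) if (h) event else "EVENT_OTHER"),
    indications = replicate(n, if (is.null(indication)) character(0)
                            else indication, simplify = FALSE))
}

#' Deterministic model-case stores
#'
#' Two textbook populations for one drug (DRUG_X) and one event (EVENT_Y),
#' reproducing the canonical 2x2 tables exactly. Case 1 (100 reports,
#' DE=1, De=9, dE=9, de=81): the event occurs in 10 percent of drug users
#' and 10 percent of other-drug users, so every disproportionality
#' measure is 1. Case 2 (90 reports, DE=2, De=8, dE=8, de=72): 20 percent
#' of drug users versus 10 percent of the background, giving RRR = 1.8,
#' PRR = 2 and ROR = 2.25. Reports outside D carry a filler drug, reports
#' outside E a filler reaction.
#'
#' @param which 1 or 2.
#' @return a \linkS4class{ReportStore}.
#' @export
fixtureModelCase <- function(which) {
  cells <- switch(as.character(which),
                  "1" = c(1L, 9L, 9L, 81L),
                  "2" = c(2L, 8L, 8L, 72L),
                  stop("invalid model case: ", which, " (expected 1 or 2)"))
  b <- cellBlock(cells[1], cells[2], cells[3], cells[4],
                 drug = "DRUG_X", event = "EVENT_Y", idPrefix = "MC")
  reportStore(b$ids, b$drugs, b$reactions, b$indications)
}

#' Deterministic two-stratum confounded store
#'
#' A Simpson's-paradox style fixture: within each indication stratum the
#' drug and the event are exactly independent (RRR = 1), but because the
#' CANCER stratum has both high drug use and a high event rate, the
#' pooled store shows RRR = 3.25. Background correction by indication
#' recovers the within-stratum null.
#'
#' @return a \linkS4class{ReportStore} of 500 reports; stratum 1 (100
#'   reports, indication CANCER) has cells 64/16/16/4, stratum 2 (400
#'   reports, indication ARTHRITIS) has cells 1/19/19/361, both for
#'   DRUG_X vs EVENT_Y.
#' @export
fixtureTwoStratum <- function() {
  a <- cellBlock(64L, 16L, 16L, 4L, "DRUG_X", "EVENT_Y",
                 indication = "CANCER", idPrefix = "SA")
  b <- cellBlock(1L, 19L, 19L, 361L, "DRUG_X", "EVENT_Y",
                 indication = "ARTHRITIS", idPrefix = "SB")
  reportStore(c(a$ids, b$ids), c(a$drugs, b$drugs),
              c(a$reactions, b$reactions), c(a$indications, b$indications))
}
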