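# brute-force linear-scan oracle for the query engine (independent of the
# inverted indexes)
bruteMatches <- function(store, query) {
  drugs <- reportDrugs(store)
  reactions <- reportReactions(store)
  indications <- reportIndications(store)
  vapply(seq_along(drugs), function(i) {
    all(query@drugAll %in% drugs[[i]]) &&
      !any(query@drugNone %in% drugs[[i]]) &&
      all(query@reactionAll %in% reactions[[i]]) &&
      !any(query@reactionNone %in% reactions[[i]]) &&
      all(query@indicationAll %in% indications[[i]]) &&
      !any(query@indicationNone %in% indications[[i]])
  }, logical(1))
}

bruteCount <- function(store, query, mask = NULL) {
  m <- bruteMatches(store, query)
  if (!is.null(mask)) m <- m & bruteMatches(store, mask)
  sum(m)
}

DRUG_POOL <- paste0("DRUG_", LETTERS[1:6])
REACTION_POOL <- paste0("EVENT_", LETTERS[1:6])
INDICATION_POOL <- c("HYPERTENSION", "DEPRESSION", "PAIN")

randomStore <- function(n, seed) {
  set.seed(seed)
  pick <- function(pool, maxK) lapply(seq_len(n), function(i)
    sample(pool, sample(0:maxK, 1)))
  reportStore(sprintf("RS%05d", seq_len(n)),
              drugs = pick(DRUG_POOL, 3),
              reactions = pick(REACTION_POOL, 3),
              indications = pick(INDICATION_POOL, 2))
}

randomQuery <- function() {
  part <- function(pool) {
    k <- sample(0:2, 1)
    terms <- sample(pool, k)
    split <- stats::runif(length(terms)) < 0.7
    list(all = terms[split], none = terms[!split])
  }
  d <- part(DRUG_POOL); r <- part(REACTION_POOL); i <- part(INDICATION_POOL)
  reportQuery(drugAll = d$all, drugNone = d$none,
              reactionAll = r$all, reactionNone = r$none,
              indicationAll = i$all, indicationNone = i$none)
}

randomTable <- function(lambda = 20) {
  cells <- stats::rpois(4, lambda) + 1L
  contingencyTable(cells[1], cells[2], cells[3], cells[4])
}

# regression-route oracles: a saturated logistic fit reproduces the sample
# odds ratio, a saturated log-binomial fit the sample risk ratio
oracleOddsRatio <- function(tab) {
  cells <- tableCells(tab)
  fit <- stats::glm(cbind(c(cells[["DE"]], cells[["dE"]]),
                          c(cells[["De"]], cells[["de"]])) ~ c(1, 0),
                    family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-12))
  unname(exp(stats::coef(fit)[2]))
}

oracleRiskRatio <- function(tab) {
  cells <- tableCells(tab)
  p1 <- cells[["DE"]] / (cells[["DE"]] + cells[["De"]])
  p0 <- cells[["dE"]] / (cells[["dE"]] + cells[["de"]])
  fit <- suppressWarnings(stats::glm(
    cbind(c(cells[["DE"]], cells[["dE"]]),
          c(cells[["De"]], cells[["de"]])) ~ c(1, 0),
    family = stats::binomial(link = "log"),
    start = c(log(p0), log(p1 / p0)),
    control = stats::glm.control(epsilon = 1e-12)))
  unname(exp(stats::coef(fit)[2]))
}

chisqTestOracle <- function(tab) {
  cells <- tableCells(tab)
  m <- matrix(cells, nrow = 2, byrow = TRUE)
  unname(suppressWarnings(stats::chisq.test(m, correct = TRUE)$statistic))
}

# exact-cell store builder used across clinical-algorithm tests
storeFromCells <- function(DE, De, dE, de, drug = "DRUG_X", event = "EVENT_Y",
                           indication = NULL, idPrefix = "CF") {
  n <- DE + De + dE + de
  hasDrug <- c(rep(TRUE, DE + De), rep(FALSE, dE + de))
  hasEvent <- c(rep(TRUE, DE), rep(FALSE, De), rep(TRUE, dE), rep(FALSE, de))
  reportStore(sprintf("%s%05d", idPrefix, seq_len(n)),
              drugs = lapply(hasDrug, function(h) if (h) drug else "DRUG_OTHER"),
              reactions = lapply(hasEvent, function(h) if (h) event
                                 else "EVENT_OTHER"),
              indications = replicate(n, indication %||% character(0),
                                      simplify = FALSE))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
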