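test_that("percentage difference of RRRs: values, limits, undefined cases", {
  expect_equal(rrrPercDiff(1, 2), -200 / 3, tolerance = 1e-12)  # -66.67
  expect_equal(rrrPercDiff(100, 101), -100 / 100.5, tolerance = 1e-12) # ~ -0.995
  expect_equal(rrrPercDiff(2, 2), 0)
  expect_equal(rrrPercDiff(3, 0), 200)
  expect_equal(rrrPercDiff(0, 3), -200)
  expect_true(is.na(rrrPercDiff(0, 0)))
  expect_true(is.na(rrrPercDiff(NA, 1)))
  # antisymmetry
  set.seed(9)
  a <- runif(50, 0, 10); b <- runif(50, 0, 10)
  expect_equal(rrrPercDiff(a, b), -rrrPercDiff(b, a))
})

test_that("drug ranking recovers a planted association and sorts correctly", {
  cfg <- syntheticConfig(
    nReports = 20000,
    associations = data.frame(drug = "DRUG_A", event = "EVENT_S", rho = 5),
    seed = 21)
  st <- generateReports(cfg)
  rk <- rankDrugsForEvent(st, c("DRUG_B", "DRUG_A", "ABSENT_DRUG"), "EVENT_S")
  e <- rankingEntries(rk)
  expect_equal(e$drug[1], "DRUG_A")           # planted RRR ~ 5 ranks first
  expect_gt(e$RRR[1], 2 * max(e$RRR[2], 0.1)) # clearly above the null drug
  expect_equal(e$drug[3], "ABSENT_DRUG")      # undefined RRR sorts last
  expect_equal(e$DE[3], 0L)
  expect_equal(e$D[3], 0L)
  expect_true(is.na(e$RRR[3]))
  expect_error(rankDrugsForEvent(st, character(0), "EVENT_S"),
               "at least one drug")
})

test_that("ranking a single drug reproduces analyzePair exactly", {
  st <- fixtureModelCase(1)
  rk <- rankingEntries(rankDrugsForEvent(st, "DRUG_X", "EVENT_Y"))
  res <- analyzePair(st, "DRUG_X", "EVENT_Y")
  expect_equal(rk$DE, unname(tableCells(res)[["DE"]]))
  expect_equal(rk$D, unname(as.integer(tableMargins(res)[["D"]])))
  expect_equal(rk$rate, reportingRate(res))
  expect_equal(rk$RRR, rrr(res))
  expect_equal(rk$RRR, 1)
})

# a store with two drugs, their combination, and controlled event counts
profileStore <- function() {
  mk <- function(prefix, n, drugs, events) {
    list(ids = sprintf("%s%04d", prefix, seq_len(n)),
         drugs = replicate(n, drugs, simplify = FALSE),
         reactions = lapply(seq_len(n), events))
  }
  blocks <- list(
    mk("A", 20, "DRUG_1", function(i) if (i <= 8) "EVENT_P" else "EVENT_Q"),
    mk("B", 20, "DRUG_2", function(i) if (i <= 4) "EVENT_P" else "EVENT_Q"),
    mk("C", 10, c("DRUG_1", "DRUG_2"),
       function(i) if (i <= 6) "EVENT_P" else "EVENT_Q"),
    mk("D", 50, "DRUG_OTHER",
       function(i) if (i <= 10) "EVENT_P" else "EVENT_Q"))
  reportStore(unlist(lapply(blocks, `[[`, "ids")),
              drugs = do.call(c, lapply(blocks, `[[`, "drugs")),
              reactions = do.call(c, lapply(blocks, `[[`, "reactions")))
}

test_that("profile comparison excludes the combination and computes RRRs", {
  st <- profileStore()
  pc <- compareDrugProfiles(st, "DRUG_1", "DRUG_2", allRows = TRUE)
  expect_equal(pc@d1Total, 20L)   # combination subtracted
  expect_equal(pc@d2Total, 20L)
  expect_equal(pc@comboTotal, 10L)
  rows <- comparisonRows(pc)
  p <- rows[rows$event == "EVENT_P", ]
  expect_equal(p$DE1, 8L)   # drug1 AND NOT drug2
  expect_equal(p$DE2, 4L)
  # E and N from the whole store: E_P = 8+4+6+10 = 28, N = 100
  expect_equal(p$RRR1, 8 * 100 / (28 * 20))
  expect_equal(p$RRR2, 4 * 100 / (28 * 20))
  expect_equal(p$percDiff, rrrPercDiff(p$RRR1, p$RRR2))
  # conservation: D1 + D2 + combo + neither = N
  expect_equal(pc@d1Total + pc@d2Total + pc@comboTotal + 50, 100)
  expect_error(compareDrugProfiles(st, "DRUG_1", "DRUG_1"), "differ")
})

test_that("profile comparison respects cutoffs and minDE", {
  st <- profileStore()
  all <- comparisonRows(compareDrugProfiles(st, "DRUG_1", "DRUG_2",
                                            allRows = TRUE))
  sel <- comparisonRows(compareDrugProfiles(st, "DRUG_1", "DRUG_2",
                                            cutoffLo = -30, cutoffHi = 30))
  expect_true(all(abs(sel$percDiff) >= 30))
  expect_true(all(sel$event %in% all$event))
  highMin <- comparisonRows(compareDrugProfiles(st, "DRUG_1", "DRUG_2",
                                                minDE = 13, allRows = TRUE))
  expect_true(all(highMin$DE1 + highMin$DE2 >= 13))
  expect_lt(nrow(highMin), nrow(all))
})

test_that("profile comparison is antisymmetric on random stores", {
  for (seed in c(31, 32)) {
    st <- randomStore(300, seed = seed)
    ab <- comparisonRows(compareDrugProfiles(st, "DRUG_A", "DRUG_B",
                                             allRows = TRUE))
    ba <- comparisonRows(compareDrugProfiles(st, "DRUG_B", "DRUG_A",
                                             allRows = TRUE))
    expect_equal(ab$event, ba$event)
    expect_equal(ab$percDiff, -ba$percDiff)
    expect_equal(ab$RRR1, ba$RRR2)
    expect_equal(ab$DE1, ba$DE2)
  }
})

test_that("DDI screen: additivity gives rateDiff 0; signs follow the convention", {
  # drug1 alone: rate 0.2; drug2 alone: rate 0.1; combination: rate 0.3
  mk <- function(prefix, n, drugs, k, event = "EVENT_Y") {
    list(ids = sprintf("%s%04d", prefix, seq_len(n)),
         drugs = replicate(n, drugs, simplify = FALSE),
         reactions = lapply(seq_len(n), function(i)
           if (i <= k) event else "EVENT_OTHER"))
  }
  blocks <- list(mk("A", 10, "DRUG_1", 2), mk("B", 10, "DRUG_2", 1),
                 mk("C", 10, c("DRUG_1", "DRUG_2"), 3))
  st <- reportStore(unlist(lapply(blocks, `[[`, "ids")),
                    drugs = do.call(c, lapply(blocks, `[[`, "drugs")),
                    reactions = do.call(c, lapply(blocks, `[[`, "reactions")))
  rows <- ddiScreen(st, "DRUG_1", "DRUG_2", allRows = TRUE)
  y <- rows[rows$event == "EVENT_Y", ]
  expect_equal(y$expected, 0.3)
  expect_equal(y$rateCombo, 0.3)
  expect_equal(y$rateDiff, 0)
  # a synergistic combination (observed > expected) must go negative
  blocks2 <- list(mk("A", 10, "DRUG_1", 2), mk("B", 10, "DRUG_2", 1),
                  mk("C", 10, c("DRUG_1", "DRUG_2"), 9))
  st2 <- reportStore(unlist(lapply(blocks2, `[[`, "ids")),
                     drugs = do.call(c, lapply(blocks2, `[[`, "drugs")),
                     reactions = do.call(c, lapply(blocks2, `[[`, "reactions")))
  rows2 <- ddiScreen(st2, "DRUG_1", "DRUG_2", allRows = TRUE)
  expect_lt(rows2$rateDiff[rows2$event == "EVENT_Y"], 0)
})

test_that("DDI screen flags an absent combination and filters by cutoffs", {
  st <- reportStore(as.character(1:20),
                    drugs = c(replicate(10, "DRUG_1", simplify = FALSE),
                              replicate(10, "DRUG_2", simplify = FALSE)),
                    reactions = replicate(20, "EVENT_Y", simplify = FALSE))
  rows <- ddiScreen(st, "DRUG_1", "DRUG_2")
  expect_true(attr(rows, "flagged"))
  expect_true(all(is.na(rows$rateCombo)))
  expect_error(ddiScreen(st, "DRUG_1", "DRUG_1"), "differ")
  # cutoff selection on a defined screen
  stp <- profileStore()
  sel <- ddiScreen(stp, "DRUG_1", "DRUG_2", cutoffLo = -0.05, cutoffHi = 0.05)
  expect_true(all(sel$rateDiff <= -0.05 | sel$rateDiff >= 0.05))
  allr <- attr(sel, "allRows")
  expect_equal(allr$rateDiff, allr[order(-abs(allr$rateDiff), allr$event),
                                   "rateDiff"])
})

test_that("planted synergistic interaction dominates the DDI screen", {
  cfg <- syntheticConfig(
    nReports = 50000,
    drugVocab = stats::setNames(c(0.1, 0.1, 0.02, 0.02),
                                paste0("DRUG_", c("A", "B", "C", "D"))),
    interactions = data.frame(drug1 = "DRUG_A", drug2 = "DRUG_B",
                              event = "EVENT_U", comboMult = 3),
    seed = 41)
  st <- generateReports(cfg)
  rows <- ddiScreen(st, "DRUG_A", "DRUG_B", allRows = TRUE)
  u <- rows[rows$event == "EVENT_U", ]
  expect_lt(u$rateDiff, 0)
  expect_equal(rows$event[which.min(rows$rateDiff)], "EVENT_U")
})

test_that("background correction removes a constructed confounder", {
  st <- fixtureTwoStratum()
  global <- rrr(dpaTable(analyzePair(st, "DRUG_X", "EVENT_Y")))
  expect_equal(global, 3.25)
  expect_gt(global, 2)
  within <- backgroundCorrected(st, analyzePair, "CANCER",
                                drug = "DRUG_X", event = "EVENT_Y")
  expect_equal(rrr(dpaTable(within)), 1)
  other <- analyzePair(st, "DRUG_X", "EVENT_Y",
                       mask = reportQuery(indicationAll = "ARTHRITIS"))
  expect_equal(rrr(dpaTable(other)), 1)
})

test_that("background correction: identity mask and empty mask", {
  st <- fixtureTwoStratum()
  # every report carries an indication, so masking on the union via two
  # calls covers the store; an all-covering single-term mask:
  stAll <- reportStore(reportIds(st), reportDrugs(st), reportReactions(st),
                       replicate(length(st), "SAME", simplify = FALSE))
  masked <- analyzePair(stAll, "DRUG_X", "EVENT_Y",
                        mask = reportQuery(indicationAll = "SAME"))
  unmasked <- analyzePair(stAll, "DRUG_X", "EVENT_Y")
  expect_identical(dpaMeasures(masked), dpaMeasures(unmasked))
  expect_warning(
    empty <- backgroundCorrected(stAll, analyzePair, "NO_SUCH_INDICATION",
                                 drug = "DRUG_X", event = "EVENT_Y"),
    "matches no reports")
  expect_true(all(is.na(dpaMeasures(empty))))
})

test_that("confounder screen ranks co-terms within the DE subpopulation", {
  n <- 10
  st <- reportStore(
    as.character(1:(n + 5)),
    drugs = c(lapply(1:n, function(i)
      c("DEXAMETHASONE", if (i <= 7) "CYCLOPHOSPHAMIDE", if (i <= 3) "CISPLATIN")),
      replicate(5, "DRUG_OTHER", simplify = FALSE)),
    reactions = c(replicate(n, "THROMBOCYTOPENIA", simplify = FALSE),
                  replicate(5, "EVENT_OTHER", simplify = FALSE)),
    indications = c(replicate(n, "MULTIPLE MYELOMA", simplify = FALSE),
                    replicate(5, character(0), simplify = FALSE)))
  cs <- confounderScreen(st, "DEXAMETHASONE", "THROMBOCYTOPENIA", topK = 5)
  expect_equal(cs$nDE, 10L)
  expect_false(cs$flagged)
  expect_false("DEXAMETHASONE" %in% cs$coDrugs$term)  # index drug excluded
  expect_equal(cs$coDrugs$term[1], "CYCLOPHOSPHAMIDE")
  expect_equal(cs$coDrugs$fraction[1], 0.7)
  expect_equal(cs$coIndications$term[1], "MULTIPLE MYELOMA")
  expect_equal(cs$coIndications$fraction[1], 1)
  # topK larger than the distinct term count returns everything
  expect_equal(nrow(confounderScreen(st, "DEXAMETHASONE", "THROMBOCYTOPENIA",
                                     topK = 50)$coDrugs), 2L)
  flagged <- confounderScreen(st, "ABSENT", "THROMBOCYTOPENIA")
  expect_true(flagged$flagged)
  expect_equal(nrow(flagged$coDrugs), 0L)
  expect_error(confounderScreen(st, "A", "B", topK = 0), "topK")
})

test_that("confounding-by-indication is detected on synthetic data", {
  cfg <- syntheticConfig(
    nReports = 30000,
    confounders = data.frame(indication = "DEPRESSION", drug = "DRUG_C",
                             event = "EVENT_T", drugMult = 8, eventMult = 8),
    seed = 51)
  st <- generateReports(cfg)
  # the indication drives both drug use and the event: a spurious signal
  expect_gt(rrr(dpaTable(analyzePair(st, "DRUG_C", "EVENT_T"))), 1.5)
  cs <- confounderScreen(st, "DRUG_C", "EVENT_T", topK = 3)
  expect_equal(cs$coIndications$term[1], "DEPRESSION")
  # background correction within the indication flattens it
  within <- backgroundCorrected(st, analyzePair, "DEPRESSION",
                                drug = "DRUG_C", event = "EVENT_T")
  expect_lt(rrr(dpaTable(within)), 1.5)
})
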