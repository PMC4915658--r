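test_that("search strings follow the openFDA dialect deterministically", {
  q <- reportQuery(drugAll = c("diazepam", "haloperidol"),
                   reactionAll = "pain")
  expected <- paste0(
    '(patient.drug.openfda.substance_name:"diazepam"',
    '+AND+patient.drug.openfda.substance_name:"haloperidol")',
    '+AND+patient.reaction.reactionmeddrapt.exact:"pain"')
  expect_equal(buildSearchString(q), expected)
  expect_equal(buildSearchString(q), buildSearchString(q))  # deterministic
  # term order is sorted regardless of input order
  q2 <- reportQuery(drugAll = c("haloperidol", "diazepam"),
                    reactionAll = "pain")
  expect_equal(buildSearchString(q2), expected)

  expect_equal(buildSearchString(reportQuery(drugAll = "X")),
               'patient.drug.openfda.substance_name:"x"')
  # multi-word preferred terms stay quoted as phrases
  expect_match(buildSearchString(reportQuery(reactionAll = "ABDOMINAL PAIN")),
               '"abdominal pain"', fixed = TRUE)
  # negations render as +AND+NOT+(field:"term")
  expect_equal(
    buildSearchString(reportQuery(drugAll = "imatinib", drugNone = "nilotinib")),
    paste0('patient.drug.openfda.substance_name:"imatinib"',
           '+AND+NOT+(patient.drug.openfda.substance_name:"nilotinib")'))
  # .exact is configurable per field class
  expect_match(buildSearchString(reportQuery(indicationAll = "DEPRESSION")),
               "drugindication.exact", fixed = TRUE)
  expect_false(grepl(".exact", buildSearchString(
    reportQuery(indicationAll = "DEPRESSION"), exactIndication = FALSE),
    fixed = TRUE))
  expect_error(buildSearchString(reportQuery()), "empty query")
  expect_error(buildSearchString(reportQuery(drugNone = "x")),
               "purely negative")
})

test_that("api queries enforce the service's pagination caps", {
  expect_error(apiQuery(search = "x", limit = 101), "limit at 100")
  expect_error(apiQuery(search = "x", skip = 5001), "skip at 5000")
  q <- apiQuery(search = "x", limit = 100, skip = 5000)
  expect_equal(q$limit, 100L)
})

test_that("fetchTotal reads meta totals, zero-match bodies and bad schemas", {
  dir <- withr::local_tempdir()
  writeKey <- faersSignal:::writeFixture
  key <- faersSignal:::requestKey
  writeKey(dir, key(""), list(meta = list(results = list(total = 4883922))))
  writeKey(dir, key('patient.drug.openfda.substance_name:"nomatch"'),
           list(error = list(code = "NOT_FOUND", message = "No matches found!")))
  writeKey(dir, key('patient.drug.openfda.substance_name:"broken"'),
           list(meta = list(disclaimer = "no results member")))
  be <- remoteStore(fixtureDir = dir)
  expect_equal(fetchTotal(be, NULL), 4883922L)
  expect_equal(countReports(be, reportQuery()), 4883922L)
  expect_equal(fetchTotal(be, 'patient.drug.openfda.substance_name:"nomatch"'), 0L)
  expect_equal(countReports(be, reportQuery(drugAll = "NOMATCH")), 0L)
  expect_error(fetchTotal(be, 'patient.drug.openfda.substance_name:"broken"'),
               "schema mismatch")
  expect_error(fetchTotal(be, "unrecorded-search"), "no recorded fixture")
})

test_that("fetchCount parses term lists and flags the 100-term cap", {
  dir <- withr::local_tempdir()
  writeKey <- faersSignal:::writeFixture
  key <- faersSignal:::requestKey
  cf <- "patient.reaction.reactionmeddrapt.exact"
  writeKey(dir, key("", cf), list(results = list(
    list(term = "RASH", count = 30), list(term = "PAIN", count = 20),
    list(term = "NAUSEA", count = 10))))
  big <- lapply(1:100, function(i) list(term = sprintf("T%03d", i), count = 200 - i))
  writeKey(dir, key('patient.drug.openfda.substance_name:"busy"', cf),
           list(results = big))
  be <- remoteStore(fixtureDir = dir)
  lt <- listTerms(be, "reaction")
  expect_equal(nrow(lt), 3L)
  expect_equal(lt$term[1], "RASH")
  expect_false(attr(lt, "truncated"))
  lt100 <- listTerms(be, "reaction",
                     restrict = reportQuery(drugAll = "BUSY"))
  expect_equal(nrow(lt100), 100L)
  expect_true(attr(lt100, "truncated"))
  expect_error(listTerms(be, "dosage"), "unknown field")
})

test_that("fixture-replayed backend reproduces local contingency cells exactly", {
  st <- generateReports(syntheticConfig(nReports = 400, seed = 23))
  dir <- withr::local_tempdir()
  pairs <- expand.grid(drug = c("DRUG_A", "DRUG_B", "DRUG_C"),
                       event = c("EVENT_Y", "EVENT_R", "EVENT_S", "EVENT_T"),
                       stringsAsFactors = FALSE)
  queries <- list()
  for (i in seq_len(nrow(pairs))) {
    queries <- c(queries, list(
      reportQuery(drugAll = pairs$drug[i]),
      reportQuery(reactionAll = pairs$event[i]),
      reportQuery(drugAll = pairs$drug[i], reactionAll = pairs$event[i])))
  }
  recordFixtures(st, dir, queries = queries)
  be <- remoteStore(fixtureDir = dir)
  for (i in seq_len(nrow(pairs))) {
    local <- buildContingency(st, reportQuery(drugAll = pairs$drug[i]),
                              reportQuery(reactionAll = pairs$event[i]))
    remote <- buildContingency(be, reportQuery(drugAll = pairs$drug[i]),
                               reportQuery(reactionAll = pairs$event[i]))
    expect_identical(tableCells(local), tableCells(remote))
  }
})

test_that("count-list truncation propagates into the profile comparison", {
  n <- 130
  st <- reportStore(
    sprintf("T%04d", 1:(2 * n)),
    drugs = c(replicate(n, "DRUG_A", simplify = FALSE),
              replicate(n, "DRUG_B", simplify = FALSE)),
    reactions = c(lapply(1:n, function(i) sprintf("REAC_%03d", i)),
                  replicate(n, "EVENT_COMMON", simplify = FALSE)))
  dir <- withr::local_tempdir()
  q1 <- reportQuery(drugAll = "DRUG_A", drugNone = "DRUG_B")
  q2 <- reportQuery(drugAll = "DRUG_B", drugNone = "DRUG_A")
  combo <- reportQuery(drugAll = c("DRUG_A", "DRUG_B"))
  recordFixtures(st, dir, queries = list(q1, q2, combo),
                 countFields = "reaction")
  be <- remoteStore(fixtureDir = dir)
  pc <- compareDrugProfiles(be, "DRUG_A", "DRUG_B", allRows = TRUE)
  expect_true(pc@truncated)
  # the local store sees every event, the capped backend only 100
  pcLocal <- compareDrugProfiles(st, "DRUG_A", "DRUG_B", allRows = TRUE)
  expect_false(pcLocal@truncated)
  expect_lt(nrow(comparisonRows(pc)), nrow(comparisonRows(pcLocal)))
  # the local engine can emulate the cap for missed-signal demonstrations
  pcCapped <- compareDrugProfiles(st, "DRUG_A", "DRUG_B", allRows = TRUE,
                                  truncateCounts = 100)
  expect_true(pcCapped@truncated)
})

test_that("purely negative remote counts raise a typed error", {
  dir <- withr::local_tempdir()
  faersSignal:::writeFixture(dir, faersSignal:::requestKey(""),
                             list(meta = list(results = list(total = 10))))
  be <- remoteStore(fixtureDir = dir)
  expect_error(countReports(be, reportQuery(drugNone = "X")),
               "purely negative")
  expect_error(remoteStore(), "either a live endpoint or a fixture directory")
  expect_error(remoteStore(fixtureDir = "does/not/exist"), "does not exist")
})
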