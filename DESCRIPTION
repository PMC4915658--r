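Package: faersSignal
Title: Disproportionality Analysis of Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Signal detection over spontaneous adverse-event report
    collections in the openFDA drug-event schema. Provides an indexed
    report store with a boolean query engine, 2x2 contingency-table
    disproportionality statistics (reporting rate, ROR, PRR, RRR,
    Yates-corrected chi-squared, Evans signal criteria), three clinical
    decision algorithms (ranking a medication list against a new adverse
    event, pairwise safety-profile comparison, drug-drug interaction
    screening), background correction by indication masks, a confounder
    screen, an openFDA-dialect query client with recorded-fixture replay,
    a synthetic report generator with plantable ground truth, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'query.R'
    'store.R'
    'openfda-load.R'
    'dpa.R'
    'clinical.R'
    'openfda-client.R'
    'synthetic.R'
    'io.R'
    'cli.R'
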