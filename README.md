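# faersSignal

Disproportionality analysis of spontaneous adverse-event reports, for
pharmacologists, hospital pharmacists and pharmacoepidemiologists who want
to mine FAERS-style report collections (the openFDA drug-event schema)
for drug-safety signals without a database server or a statistics
license.

## What it computes

Every analysis starts from the 2×2 contingency table of drug usage (D)
versus event occurrence (E) over a collection of N safety reports, with
cells named by intersection: DE (drug used and event occurred), De, dE,
de, and margins D = DE + De, d = dE + de, E = DE + dE, e = De + de.
On that table the package computes

- reporting rate: `Rate = DE / D`
- reporting odds ratio: `ROR = (DE·de) / (dE·De)`
- proportional reporting ratio: `PRR = (DE·d) / (dE·D)`
- relative reporting ratio: `RRR = (DE·N) / (E·D)` (observed over
  expected under independence)
- Yates-corrected chi-squared:
  `χ² = N·(|DE·de − dE·De| − N/2)² / (E·e·D·d)`, clamped at zero for
  near-balanced tables
- the Evans signal criteria (PRR > 2, χ² > 4, DE > 3; thresholds
  configurable)

A value of 1 for the three ratios means no disproportion; zero
denominators yield a typed undefined marker (`NA`), never an exception
and never a continuity-corrected ratio.

On top of the 2×2 core sit three clinical decision algorithms:

1. **Rank a medication list against a new adverse event**
   (`rankDrugsForEvent`): highest RRR first — the candidate to
   discontinue first.
2. **Compare two drugs' safety profiles** (`compareDrugProfiles`): for
   every adverse event reported with either drug (the combination
   excluded from both populations), the percentage difference of the
   RRRs relative to their mean, `(RRR₁ − RRR₂)/mean(RRR₁, RRR₂)·100`,
   bounded in ±200 % and antisymmetric.
3. **Screen a drug pair for interactions** (`ddiScreen`): per event,
   `rate_diff = (Rate_D1 + Rate_D2) − Rate_D1D2`; negative values
   (observed combination rate above the additive expectation) suggest
   synergy, positive ones antagonism.

Background correction (PRR-by-therapeutic-area) restricts every count to
an indication-defined subpopulation (`backgroundCorrected`, or the
`mask` argument anywhere), and `confounderScreen` lists the drugs and
indications co-reported within the DE subpopulation. Counts come either
from an indexed in-memory `ReportStore` (loaded from openFDA JSON /
NDJSON files or generated synthetically with plantable ground truth) or
from a `RemoteBackend` that speaks the openFDA query dialect and replays
recorded fixtures offline.

## Worked example

```r
library(faersSignal)

cfg <- syntheticConfig(nReports = 20000,
  associations = data.frame(drug = "DRUG_A", event = "EVENT_Y", rho = 5),
  seed = 42)
st <- generateReports(cfg)

rankDrugsForEvent(st, c("DRUG_A", "DRUG_B", "DRUG_C"), "EVENT_Y")
#> Drug ranking for adverse event 'EVENT_Y' (highest RRR first)
#>     drug DE   D        rate       RRR
#> 1 DRUG_A 29 438 0.066210046 5.5638694
#> 2 DRUG_B  4 362 0.011049724 0.9285482
#> 3 DRUG_C  1 406 0.002463054 0.2069793

analyzePair(st, "DRUG_A", "EVENT_Y")
#> 2x2 contingency table (drug x event)
#>       E     e   sum
#> D    29   409   438
#> d   209 19353 19562
#> sum 238 19762 20000
#> rate = 0.06621  ROR = 6.566  PRR = 6.197  RRR = 5.564  chi2(Yates) = 107.7
#> Evans signal: TRUE
```

The planted association (a 5-fold risk multiplier for DRUG_A and
EVENT_Y) is recovered: DRUG_A's RRR of 5.56 says the drug-event pair is
reported about 5.6 times more often than expected if drug and event were
independent, the two null drugs sit near 1, and the pair passes the
Evans criteria. The ranking answers "which drug to stop first" for a
patient on all three drugs who develops EVENT_Y.

A command-line interface wraps the same functions
(`inst/scripts/faers-signal`), with subcommands `dpa`, `rank`,
`compare`, `ddi`, `confounders` and `synth`, CSV/JSON writers and an
indication-mask option.

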