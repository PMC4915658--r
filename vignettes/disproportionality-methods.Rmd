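---
title: "Disproportionality analysis of spontaneous reports: model, algorithms and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality analysis of spontaneous reports: model, algorithms and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersSignal)
```

## The statistical model

Spontaneous reporting systems collect reports that each carry a set of
drugs, a set of reaction terms and a set of indications. The data are an
*open-world* sample: the denominator of true exposures is unknown, so no
absolute risk is estimable. What is estimable is *disproportionality* —
whether a drug-event pair is reported more often than the rest of the
collection would predict. The unit of analysis is the report: a report
contributes at most 1 to any cell however often a term repeats inside it.

All measures derive from the 2×2 table of drug usage versus event
occurrence with cells DE, De, dE, de and margins D, d, E, e, N. The
reporting rate DE/D alone is meaningless; it has to be set against the
background, which the three ratio measures do in slightly different ways:
ROR compares odds, PRR compares the event's share among the drug's
reports with its share among all other reports, and RRR compares the
observed DE with its expectation E·D/N under independence. On real
collections the three move together; the clinical algorithms below use
RRR, and all three are reported by `analyzePair()`.

Two deterministic model populations (`fixtureModelCase()`) pin the
arithmetic down:

```{r model-cases}
dpaMeasures(analyzePair(fixtureModelCase(1), "DRUG_X", "EVENT_Y"))
dpaMeasures(analyzePair(fixtureModelCase(2), "DRUG_X", "EVENT_Y"))
```

In case 1 the event occurs in 10 % of drug users and 10 % of other-drug
users, and every ratio is exactly 1; in case 2 (20 % versus 10 %) they
are RRR = 1.8, PRR = 2, ROR = 2.25 — the spread between the three grows
with the drug's share of the collection.

### Chi-squared with Yates' correction

The test statistic is `N·(|DE·de − dE·De| − N/2)² / (E·e·D·d)`. Written
this way the corrected difference can go *negative* for near-balanced
tables, which would spuriously inflate the statistic after squaring;
standard Yates practice clamps `|DE·de − dE·De| − N/2` at 0, and the
package does so by default (the literal unclamped form is available via
`clamp = FALSE` for parity checks). With the clamp, the formula agrees
with `chisq.test(..., correct = TRUE)` to numerical precision, which the
test suite verifies on a thousand random tables. N/2 is kept in floating
point — no integer truncation — and the cell products are computed in
double precision because margin products overflow 32-bit integers at
realistic collection sizes.

### Undefined values

Every zero-denominator case returns `NA` rather than raising or applying
a Haldane-style 0.5 correction: the measures as defined apply no
continuity correction to the ratios, and silently shrinking extreme
tables would bias exactly the sparse cells signal detection cares about.
`NA` propagates: the Evans flag is `NA` whenever PRR or chi-squared is.
The writers render `NA` as empty CSV cells and JSON nulls, never 0.

### Signal thresholds

The Evans criteria — PRR > 2, chi-squared > 4 (roughly p < 0.05), DE > 3,
strict inequalities — are conventional, not canonical; there is no
consensus on clinically significant cut-offs. They are therefore plain
configuration (`prrMin`, `chi2Min`, `deMin`) with the conventional
defaults, as are the ±75 % profile-comparison cut-offs and the
−0.03/+0.035 rate-difference cut-offs of the interaction screen. The
asymmetric interaction defaults keep slightly more of the synergy side;
the sign convention is fixed so that *negative* rate differences mean
the combination is reported above its additive expectation.

## The clinical algorithms

**Ranking (one event, many drugs).** For each drug of a medication list,
DE and D are extracted and the rate and RRR computed against the shared E
and N. Entries sort by RRR descending (ties: rate, then name); drugs
absent from the collection get undefined RRR and sort last.

**Profile comparison (two drugs, all events).** Reports carrying *both*
drugs are removed from both single-drug populations — including the
event-level counts — so each population means "this drug without the
other". For every event co-reported with either drug, the two RRRs are
compared by their percentage difference relative to the mean of the two,
`rrrPercDiff()`, bounded in ±200 %. A difference of 1 between RRRs 1 and
2 gives −66.7 % (meaningful); between 100 and 101 it gives −1 % (noise).
When exactly one RRR is 0 the bound ±200 is returned; when both are 0 or
either is undefined the row carries `NA` and is excluded from cut-off
selection.

**Interaction screen (two drugs versus their combination).** Expected
rate under additivity is the sum of the single-drug rates on the
combination-excluded populations; `rate_diff = expected − observed`.
With no combination reports at all, every combination rate is undefined
and the result is flagged rather than filtered.

**Background correction and confounders.** Any signal can be an artifact
of the treated disease (confounding by indication). Restricting every
count to reports carrying a given indication (a query *mask*) removes
that pathway; `confounderScreen()` suggests candidate masks by ranking
the drugs and indications co-reported inside the DE subpopulation. The
two-stratum fixture makes the mechanism concrete: drug and event are
independent inside each stratum, yet pooling shows RRR = 3.25.

```{r simpson}
st <- fixtureTwoStratum()
rrr(analyzePair(st, "DRUG_X", "EVENT_Y"))
rrr(backgroundCorrected(st, analyzePair, "CANCER",
                        drug = "DRUG_X", event = "EVENT_Y"))
```

## The query engine and backends

Queries are conjunctions of required and excluded terms over the three
fields; terms are upper-cased and trimmed on ingest and at query
construction, and matching is exact on the normalized string — reaction
preferred terms are conventionally upper case while user input is mixed
case, and drug-name cleaning or ontology mapping is deliberately out of
scope. Counting uses inverted indexes (term → report positions), with a
brute-force linear scan serving as the test oracle. Reports without any
cleaned drug name stay in the store by default because removing them
silently would distort d, e and N; `dropUndrugged()` gives the opposite
policy explicitly.

The remote backend renders the same queries into the openFDA search
dialect (field-qualified, quoted, sorted terms; `+AND+` conjunctions;
`+AND+NOT+(...)` negations; `.exact` on reaction and indication fields
but not substance names, both overridable). Contingency cells are always
derived from four *positive* searches (N, D, E, DE), so the undocumented
precedence of negated searches never matters for the core path; a purely
negative count is refused with a typed error. The service caps count
lists at 100 terms and pagination at skip 5000 / limit 100; a list of
exactly 100 terms is flagged truncated and the flag propagates into
profile comparisons, whose event universe may then be incomplete — the
mechanism by which real signals can be missed when working through the
capped service, demonstrable locally via `truncateCounts = 100`. All
client tests replay recorded fixture responses; nothing in the test
suite or the examples touches the network.

## The synthetic generator

`generateReports()` draws each drug and indication independently per
report with its marginal probability and each event with its baseline
probability times the risk multiplier ρ of every planted association
whose drug is present (multiplicative risk, so ρ is directly plantable),
times confounder and interaction multipliers; effective probabilities
are clamped to [0, 1]. Under this model the expected RRR for a planted
pair is attenuated by the drug's own contribution to the background:

RRR = ρ / (1 + p_D·(ρ − 1)),

with p_D the drug's marginal probability — close to ρ only while the
drug is rare. The default vocabulary therefore uses p_D = 0.02, a
realistic marginal for a commonly reported drug: at ρ = 5 the expected
RRR is 5/1.08 ≈ 4.6. Clamping biases recovered RRR downward for
non-rare events, so recovery tests use baselines of a few percent.
Recovery is tested at n = 50,000 reports over 20 seeds (median planted
RRR within [4, 6]; null median within [0.8, 1.2]); the null-calibration
and monotonicity properties run at n = 20,000, sizes chosen to keep the
whole suite brisk while leaving binomial noise well inside the asserted
bands.

What the generator emulates: per-report term sets with controllable
marginals, planted associations, indication-mediated confounding and
combination-only interaction effects, round-trippable through the
openFDA NDJSON schema. What it does not emulate: duplicate and versioned
reports, under-reporting dynamics, correlated prescribing outside the
indication pathway, dosages, demographics, or uncleaned drug-name noise.
Passing recovery tests therefore show the estimators are correct under
the stated generative model, not that real FAERS signals are unbiased —
on real data, confounding and reporting artifacts remain the dominant
error source, which is exactly why the confounder screen and background
correction exist.

## Numerical and design choices

- Counts are integers throughout; derived margins switch to doubles
  before any product.
- The profile-comparison denominator is the mean of the two RRRs. The
  alternative reading — the mean of the single *difference* — is
  degenerate (it forces ±100 % for every event) and was rejected.
- Duplicate report ids keep the last occurrence with a warning (the
  upstream service serves versioned reports); reports without an id are
  skipped, never silently.
- `minDE` defaults to 0: on local stores there is no reason to discard
  sparse rows by default, and the service-like behaviour is available
  explicitly.
- Event universes are enumerated fully from the local store; truncation
  is an explicit emulation mode, never an implicit default.
- Generated collections are reproducible: the generator seeds its own
  RNG stream and restores the caller's.

## Known limitations

Signals are hypothesis-generating only; none of the measures is a risk
estimate, and no causality assessment, dose accounting, Bayesian
shrinkage (BCPNN/EBGM) or confidence intervals for ROR/PRR are provided.
Drug-name cleaning and MedDRA ontology aggregation are out of scope: a
term is whatever normalized string the source carried. The live client
is best-effort (the emitted dialect is pinned by fixtures; live parity
of negation precedence is not guaranteed) and is never exercised by the
test suite.
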