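---
title: "Computing colorectal-surgery quality indicators from two data sources: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing colorectal-surgery quality indicators from two data sources: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcqi)
```

## The problem

National surgical audits publish quality indicators — numerator/denominator
percentages over an eligible patient population — that hospitals compute from
manually abstracted registry data. The same indicators should, in principle,
be computable directly from the structured part of an electronic medical
record (EMR). Whether that works in practice is a data-quality question: are
the required items *available in a structured format*, *complete*, and
*correct* (consistent in effect with the abstracted data)?

`crcqi` implements the full comparison pipeline for a colorectal-cancer
surgery indicator set: a declarative indicator engine, deterministic patient
matching across the two sources, diagnostic-accuracy statistics with a
covariance-corrected test for proportions from overlapping samples, per-item
data-quality measurement, and a synthetic paired-cohort generator so the
whole pipeline runs without access to protected patient data.

## The indicator engine

Indicators are shipped as a JSON document of predicate trees
(`indicator_definitions()`): each indicator has a denominator, usually a
numerator, and an exclusion predicate, over 14 data items (operation date,
year of birth, procedure, operation urgency, primary location/diagnosis, cT,
pN, pM, examined lymph nodes, circumferential margin, colonoscopy,
chemotherapy, meeting date, radiotherapy start date). Every item carries an
explicit status: `present`, `absent`, `unknown` (recorded as unknown — treated
like absent), or `unstructured` (free text only).

Predicates evaluate under three-valued Kleene logic: a leaf touching a
non-`present` item is *undetermined*; AND short-circuits on a determinate
failure, OR on a determinate success. A patient is selected only by a fully
*satisfied* predicate — missing data can therefore hide patients from a
selection but never silently misclassify them. An element is *computable* on
a dataset only if every required item is available in a structured format
somewhere in that dataset; elements whose items live only in free text (the
pathology-derived stage, node count and margin items in the default EMR
world) are reported non-computable rather than zero.

Design choices where the indicator set itself is silent:

* **Age** (adjuvant-chemotherapy indicators) is operation-year minus year of
  birth — only the birth year is recorded.
* **Stage III** means pN ∈ {N1, N2} and pM = M0.
* **"Before surgery"** (meeting, preoperative radiotherapy, complete
  imaging) means strictly before the operation date; a same-day event counts
  as not-before. The correctness rules speak only of "before" vs "after", so
  ties are resolved conservatively.
* **Diagnosis–procedure linkage**: a diagnosis dated after the operation is
  not accepted as its indication (the EMR stores no explicit relation), and a
  missing primary/recurrent distinction does not block selection — the codes
  are too coarse, so the query is generalised, which is exactly how recurrent
  carcinomas leak into an EMR-based selection.
* **Exclusion criteria** (recurrent carcinoma, TEM resection, 'resection' via
  colonoscopy, previous radiotherapy) have no structured representation in
  either source; they are optional boolean items defaulting to `absent`. In
  the default lenient mode an absent flag means not-excluded; a strict mode
  treats it as undetermined and drops the record from selections.
* **Operation urgency** arrives in 8 EMR categories mapped onto the 4
  registry categories by a configurable table; the deliberately unmappable
  category (`extra`) yields an undetermined electiveness and a
  standardisation problem log entry.
* The radiotherapy indicator's inclusion rule is unstated in the source
  definition; by default its population is T3/T4 rectum carcinoma regardless
  of procedure, with `require_resection_for_7 = TRUE` as the narrow variant.
* The two audit-submission numerators (indicators 1 and 6a) are excluded
  from computation by design; their denominators are computed. Indicator 8b
  is a bare volume count.
* Reported percentages are rounded half-up to integer percent; raw ratios
  are always retained.

## Patient matching

Without shared identifiers, patients are blocked on exact (gender, year of
birth, operation date) and blocks are resolved by Jaccard similarity of
procedure-class sets: the block's maximum-cardinality,
maximum-total-similarity assignment is computed exactly (blocks are small,
enumeration is feasible), pairs present in *every* optimal assignment are
matched, and records whose optimal partner is not unique are flagged
ambiguous and counted unmatched. We deliberately do not break genuine
similarity ties lexicographically: identity is not decidable from the
available fields in that case, and a silent guess would contaminate every
downstream agreement statistic. The procedure is symmetric in the two
sources and independent of row order. An optional `date_window` tolerates
small operation-date disagreements (transfer-of-care records).

## Agreement statistics

For each computable element the two selections are cross-classified over
matched pairs: `tp` (selected by both), `ref_only`, `test_only`, and `tn`
(pairs in both universes selected by neither). With the registry as
reference standard: sensitivity = tp/(tp + ref_only) and PPV =
tp/(tp + test_only). Negatives are defined *within each source's eligible
universe* — for a numerator element, its denominator selection — so
specificity = tn / (n_ref − ref positives) and NPV = tn / (n_test − test
positives). This convention is not spelled out in audit practice; it is the
one that makes the published specificity and NPV cells mutually consistent,
except for one published NPV (3/44) that no universe in the published
cross-tabulations yields — the package reports the convention-derived value
(3/22) and documents the discrepancy rather than matching it. Statistics
with zero denominators are undefined (`NA`, rendered "-"), never errors.
Likelihood ratios derive from sensitivity and specificity.

Because the two percentages are estimated on overlapping samples (most
patients appear in both denominators), their difference is tested with a
covariance-corrected z-test: among the m shared subjects let q1, q2, q11 be
the proportions positive on measure 1, measure 2 and both; then

    cov(p1_hat, p2_hat) = m (q11 − q1 q2) / (n1 n2)
    var(p1_hat − p2_hat) = p1(1−p1)/n1 + p2(1−p2)/n2 − 2 cov

with a standard-normal reference, two-sided, no continuity correction, and a
small-sample warning when any expected cell is below 5. At m = 0 this is
exactly the unpooled two-proportion z-test. The test suite validates the
covariance term against a 10^5-replicate paired bootstrap (agreement to
~1e-5 in p-value on the published sample geometry) and checks the empirical
type-I error on 10^4 null simulations (5% ± 1.5 points).

## Data quality

* **Structured availability** is a dataset-level property per item: available
  unless every record stores it as free text.
* **Completeness** is the share of applicable records with status `present`;
  `unknown` and `unstructured` count as absent. Four items (colonoscopy,
  chemotherapy/medication, meeting date, radiotherapy start date) do not
  apply to every operated patient; they are reported (bracketed) but excluded
  from the completeness average, which is the unweighted mean over the ten
  universally-applicable items, with unavailable items contributing 0.
* **Correctness** is effect-equivalence over matched pairs where both sources
  record the item: dates must fall on the same side of the operation date,
  procedures in the same resection class, urgency in the same harmonised
  elective/non-elective class, diagnoses in the same location class, counts
  and margins on the same side of their indicator thresholds (≥10 nodes,
  ≤1 mm). The rules are symmetric in the two sources. The correctness average
  is the unweighted mean over items with at least one evaluable pair.
* Completeness in the paired report is computed over each source's matched
  records, so both columns describe the same patients.

## The synthetic world

The generator states one world and keeps it fixed: ~79 patients resected in
one reporting year, all present in the EMR (the source system), abstracted
into the registry with coverage 75/79. Clinical marginals are simple
configurable distributions — only the degradation process, not the clinical
marginals, drives the analysis: tumour location categorical
(colon/rectosigmoid/rectum ≈ 0.52/0.08/0.40), elective rate 0.55, cT mostly
T3, stage distribution giving roughly a third stage III among colonic
resections, lymph-node counts Poisson(14), margins exponential (mean
≈ 6.7 mm, ~14% ≤ 1 mm), meetings before the operation 97% of the time,
preoperative radiotherapy for 90% of T3/T4 rectum patients.

Degradation defaults mirror the published per-item profile: registry
completeness 1.0 except cT 0.39, margin 0.24, node count and chemotherapy
0.99, meeting date 0.85; EMR completeness 1.0 except colonoscopy 0.80,
chemotherapy 0.97, meeting date 0.79; the five pathology-derived items are
free-text-only in the EMR; EMR effect-error rates are one minus the
published correctness (procedure 0.03, urgency 0.05, diagnosis 0.09,
colonoscopy 0.17, chemotherapy 0.79, meeting date 0.02). Twenty percent of
the missingness mass is recorded as an explicit `unknown`. Extraction
anomalies: missing diagnosis 5%, diagnosis dated after the operation 9%,
imprecise (primary-flag-less) codes 5%, wrong procedure class 1.5%. The
registry is degraded only by missingness unless a registry error rate is
explicitly configured — how often the abstraction itself is wrong is not
knowable from the two sources alone. Radiotherapy-date completeness is
interpreted as recording probability *given the event occurred*; the low
printed completeness of that item arises as prevalence × recording.

Errors are injected *effect-visibly* (a date crosses the operation date, a
stage flips class, a count crosses the 10-node threshold), because
correctness is defined by effect on indicators: an error the indicator logic
cannot see would be unmeasurable by construction.

What a green test does establish: the engine, matcher and statistics are
internally consistent, recover configured rates, and reproduce the published
accuracy and quality arithmetic exactly on deterministic fixtures. What it
does not establish: anything about real Dutch hospital data — the generator
has no free text, no referral gaps beyond simple unmatched records, no
coding-system drift, and clinical marginals chosen for plausibility, not
estimated from data.

## Numerical choices

Half-up rounding for printed percentages (the IEEE half-even default would
print 84.5% as 84%). Percentage undefined whenever its denominator is zero
or an element is non-computable. The overlap-test variance is floored at
zero before the square root; a zero variance with unequal proportions is a
classed error. Matching enumeration is capped (50,000 assignments per
block) — far beyond any realistic block of same-key surgical patients.
Fixture construction is fully deterministic; generator output is
byte-reproducible for a given config and seed.

## Known limitations

* Correctness is cross-source consistency, not chart-adjudicated truth; two
  consistently wrong sources count as correct, as in any two-source design.
* The registry is treated as reference standard; accuracy statistics inherit
  that asymmetry.
* The NPV universe convention is a documented choice; one published cell
  disagrees with every convention we could derive (see the agreement
  section).
* No probabilistic linkage: patients whose key fields disagree across
  sources (beyond the optional date window) stay unmatched.
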