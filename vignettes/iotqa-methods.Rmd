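---
title: "From noisy device streams to FHIR: the iotqa methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From noisy device streams to FHIR: the iotqa methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iotqa)
```

## The problem

Consumer IoT medical devices — blood-pressure monitors, pulse oximeters,
weight scales — transmit observation streams that are heterogeneous in
format, imperfect in content (malformed timestamps, out-of-range readings,
missing fields, transmission gaps) and of unknown reliability. Before such
data can feed clinical decision-making it must be (a) cleaned against
explicit constraints, (b) quantitatively quality-scored so unreliable
devices can be excluded wholesale, and (c) translated into a common
interoperable representation. `iotqa` implements that pipeline end to end
for record-structured vital-sign streams, with HL7 FHIR as the target
representation, and ships a seeded synthetic stream generator so the whole
chain is testable without hardware.

## Data model

An observation record is a timestamped triple of measurements — for a
blood-pressure monitor: diastolic pressure, systolic pressure, heart rate —
each carrying a code (a UUID identifying the measurement type), an integer
value, and a unit string. A device dataset couples the ordered records with
a device specification (type, cadence in records/day) and the observation
period in days; `cadence × period_days` is the device's *operating cycle*,
the number of records a fully available device would deliver. Datasets
read/write losslessly between a JSON dialect (an `items` array of
observation objects with positional `measurements`) and an XML dialect
(`observation` elements with `measurement/measuredValue/unit/code`
children). Dates and times stay raw strings at ingestion; conformance
checking belongs to the cleaner, not the reader.

## Cleaning

Cleaning is a three-step pass driven by a declarative rule table
(`bpm_rules()`, or a YAML file): each element has a semantic type, a
required flag, and exactly one constraint — a format pattern for dates and
times, a UUID well-formedness check for codes, a numeric range for values,
a fixed string for units.

1. **Validation** records one violation per breached (element, rule) pair,
   split by cause into *erroneous* (present but invalid) and *missing*.
2. **Correction/dropping.** A breach on a *required* element (date, time,
   any measurement code) invalidates the whole record: it is dropped, and
   the drop counts as **one** corrective action regardless of how many
   elements it breached. This counting rule is what makes the report
   arithmetic consistent: total actions = per-element anomaly tallies with
   dropped records counted once.
3. **Completion.** Optional-element breaches are repaired in place:
   out-of-range values are invalidated and re-estimated by kNN imputation;
   values missing at random are completed by a decision-tree imputer;
   missing or wrong units are filled with their fixed value.

The report metrics are exact ratios: accuracy
`(records − actions)/records`, the faulty fraction `1 − accuracy`, and
completion `(records − dropped)/records`. Accuracy and faulty are exact
complements by construction; accuracy ≤ completion always, since drops are
a subset of actions. Percentages are *rendered* at two decimals with
half-up rounding; internal arithmetic is full precision.

### Imputation parameters

* **kNN** (erroneous values): `k = 3`, features are the record's other two
  vitals plus its time-of-day slot, z-score standardized over the donor
  pool, Euclidean distance, imputed value = mean of the `k` nearest donors.
  With fewer than `k` donors the imputer falls back to a moving average of
  the neighbouring observations (with a warning). Donors for a column are
  the originally observed values only — imputations are never chained into
  later imputations of the same column.
* **Decision tree** (missing values): a C4.5-style tree, depth ≤ 3,
  features discretized into ≤ 4 quantile bins, splits chosen by information
  gain *ratio* on the binned target, rows with a missing feature ignored in
  that feature's gain (the gain down-weighted by the observed fraction),
  leaves predicting the mean of their observed targets. The method is
  implemented in-package because its defining property — missing feature
  values ignored during gain computation — is not what CART-style library
  trees do.
* Both imputers round to integers and, by construction (means of in-range
  donors), land inside the value's valid range, so a cleaned dataset
  re-validates with zero violations and cleaning is idempotent.

A strategy selector (`select_completion_strategy()`) exposes the
variation-based tiering used when series-level completion is wanted:
coefficient of variation < 0.05 with ≥ 2 samples/day → last value;
CV < 0.2 with frequent sampling → moving average; higher variation or
infrequent sampling → machine-learning imputation. The thresholds are
package defaults (the tiers are qualitative in origin) and are exposed as
arguments.

## Quality estimation

Three channels combine into one gate decision per device:

* **Operational availability** (`uptime / operating_cycle`, capped at 1):
  delivered records over expected records. By default the numerator is
  the *post-cleaning* record count; `use_raw = TRUE` switches to the raw
  delivered count. Both conventions appear in practice; the automatic
  (cleaned-count) mode is the default.
* **Faulty data**: the cleaning report's faulty fraction.
* **Reliability**: ICC(2,1) — two-way random effects, absolute agreement,
  single measurement — computed natively from the ANOVA mean squares
  (`(MSR − MSE) / (MSR + (m−1)MSE + (m/n)(MSC − MSE))`). The reliability
  matrix lays subjects out as calendar days and repeated measurements as
  the cadence slots within the day, one matrix per vital, averaged across
  vitals; days with gaps are excluded. The layout is a package choice (the
  repeated-measures structure of such streams admits several) and is
  swappable by passing a matrix directly. Negative estimates are passed
  through unclamped and flagged; a zero-variance matrix returns 1 with a
  warning. Reliability may instead be supplied as an external input
  (`icc_pct`), e.g. from a dedicated test–retest study.

Overall quality is the weighted combination
`(availability − faulty) × 0.7 + ICC × 0.3` on the percent scale, with the
weights and the 90 % threshold configurable (`run_config()`). The gate is
strict: a device is kept only when its overall quality *exceeds* the
threshold; discarded devices are erased from all downstream outputs.

**Rounding convention.** Report tables render availability and faulty data
at two decimals before the weighted combination, and the combination
itself is then rendered at two decimals. This matters at the last digit:
with full-precision inputs the Withings reference row would render 92.48
rather than the tabulated 92.47. `overall_quality()` itself is exact;
the rendering happens in `quality_report()`.

## Interoperability

Cleaned XML is lifted into an **ontology tree**: one node per distinct
element path (repeated elements merge, their text contents accumulating as
leaf instances). Dataset attributes are matched against a bundled FHIR R4
attribute catalogue through two channels:

* **Structural similarity** is the Sørensen–Dice coefficient over
  *overlapping* character-bigram multisets of the upper-cased names,
  tokenized at dot boundaries: `2|A ∩ B| / (|A| + |B|)`. Overlapping
  bigrams are the only reading under which identical names score exactly
  1 and the pair-count arithmetic is consistent; non-overlapping chunking
  (e.g. splitting PATIENT into PA/TI/ENT) breaks both properties and was
  rejected.
* **Semantic similarity** flattens each node to its
  (name tokens, relationship names, instance values) triple and scores the
  harmonic mean of precision and recall under a pluggable term-match
  backend. Precision counts the proposed node's terms matched in the
  reference; recall counts the reference's terms matched by the proposal —
  counting matched terms on each side independently is the package's
  choice among the readings the harmonic-mean definition admits, and the
  one that keeps the measure discriminative when one side has many more
  terms. The default backend is a bundled lexicon of clinical-attribute
  synonym sets (patient/subject, value/quantity/measured,
  date/time/effective, ...); any object with a `matches(a, b)` predicate —
  e.g. an adapter over a distributed-semantics fingerprint service — can
  replace it.

The **overall mapper** averages the two channels per
(dataset attribute, candidate) pair — a pair absent from one channel scores
0 there — and selects per attribute: any candidate whose mean strictly
exceeds the 90 % threshold wins (`above_threshold`); otherwise the argmax
(`argmax_fallback`), ties broken lexicographically so mapping is fully
deterministic. Kept records are then emitted as FHIR Observation resources
(one per record, `effectiveDateTime` from date+time, one component per
vital with `valueQuantity`), serializable as a JSON or XML Bundle, with
value multisets conserved exactly.

The package ships the reference similarity tables of the original mapping
evaluation as CSV fixtures (`reference_similarity_tables()`). The
non-identity structural scores in that reference (e.g. 82 for
measuredValue against Observation.valueQuantity) are artifacts of the
reference implementation and are not reproducible from the Dice definition
under any tokenization we enumerated; the package therefore validates its
structural channel against a brute-force Dice oracle plus the identity
rows, and uses the tabulated scores only as *inputs* to the mapper in
golden tests. Of the twelve reference overall means, eleven are exact
pairwise averages of the tabulated channel scores; the `sub-category` row
is not (its tabulated aggregate follows an unstated rule), and the mapper's
arithmetic answer for it — Observation.category at 33.0 — is asserted
as such.

## The synthetic generator

`generate_stream()` emulates a device transmitting `cadence` records/day on
a fixed daily grid. Default vital models: diastolic N(80, 8) on
[40, 120] mmHg, systolic N(120, 10) on [70, 200] mmHg, heart rate N(70, 8)
on [30, 220] beats/min — a normotensive adult at rest, with ranges equal
to the default rule constraints so un-injected values always validate.
Anomalies are injected per an explicit error profile (per-element erroneous
and missing counts plus whole-record gaps), each in its own record,
placed uniformly at random under the seed; erroneous values are malformed
strings for dates/times/codes/units and below-floor values for numerics
(mirroring how real device glitches show up as impossible low readings).
Injected counts are exactly recoverable by the validator — the closed-loop
property the cleaning tests rely on. `make_table_fixture()` instantiates
the four reference blood-pressure monitors of the two-month (61-day,
4 records/day) evaluation, reproducing their record tallies and per-element
anomaly profiles exactly; only the *counts* reproduce the reference — the
measurement values are synthetic draws, so value-level statistics (and
hence natively computed ICCs) are not those of the original patient data.
The bundled `bpm_device_icc()` reliability inputs fill that gap for runs
that want the reference quality scores.

What passing tests therefore show: the metric arithmetic, counting rules,
gating and mapping reproduce the reference tallies and scores exactly, and
the estimators (ICC, imputers, Dice) are correct against independent
oracles. What they do not show: performance on real streams, whose error
processes are not uniform-random and whose vitals are not i.i.d. Gaussian.

## Problem sizes and numerical choices

The test suite and acceptance script run four 244-record devices end to end
(seconds on one CPU); ICC oracle checks use 50 random small matrices at
tolerance 1e-10, and estimator recovery uses 20 Monte-Carlo replicates of a
200-subject × 4-session two-way random-effects model (a single draw at that
size has sampling error of the same order as the ±0.05 tolerance; the
replicate mean tests unbiasedness rather than one draw's luck). Degenerate
inputs are handled explicitly: empty streams, all-missing series
(unrecoverable-series error), zero-variance reliability matrices, all-zero
similarity rows (flagged, resolved to the lexicographically first catalogue
attribute), and infeasible error profiles (configuration error listing the
overflow).

## Known limitations

* The constraint language covers the formats/ranges/fixed values/UUIDs a
  vital-sign monitor needs plus one cross-field rule (systolic >
  diastolic, off by default); arbitrary cross-field predicates and
  per-patient personalized constraints are out of scope.
* The semantic backend is a lexicon, not a trained semantic space; scores
  are meaningful relatively (for ranking candidates), not absolutely.
* The generator does not simulate physiological dynamics (circadian
  cycles, hypertensive episodes) or multi-patient populations.
* FHIR output covers Observation resources with device provenance;
  Patient/Practitioner resources are emitted only insofar as the mapped
  attributes populate them, and no terminology binding (LOINC/SNOMED) is
  attempted.
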