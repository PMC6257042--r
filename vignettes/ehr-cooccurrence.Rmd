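---
title: "EHR prevalence and co-occurrence statistics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EHR prevalence and co-occurrence statistics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omopfreq)
library(data.table)
set.seed(1)
```

## The counting model

`omopfreq` treats an EHR extract as a collection of per-patient *concept
sets*. All rows of the three OMOP event tables (`condition_occurrence`,
`drug_exposure`, `procedure_occurrence`) are reduced to unique
`(person_id, concept_id)` pairs inside a dataset window; each included
patient's non-zero demographic concept ids (gender, race, ethnicity from
the `person` table) are added to their set. A patient enters the dataset —
and the denominator `N_P` — only if at least one clinical event falls in
the window; demographics alone never qualify a patient.

From the concept sets, two families of counts are formed:

* the single count `N_C`, the number of patients whose set contains `C`,
  giving EHR prevalence `P_EHR(C) = N_C / N_P`;
* the pair count `N_{C1,C2}`, the number of patients whose set contains
  both concepts, giving co-occurrence frequency `N_{C1,C2} / N_P`. Pairs
  are unordered, stored once with `concept_id_1 < concept_id_2`, and
  self-pairs are not emitted (a self-pair is just the single count).

The model is deliberately blind to time *within* the window and to
hierarchy: a concept only counts when its exact id is coded, descendant
concepts are not rolled up, and nothing is inferred about which concept of
a pair came first. EHR prevalence is an observational quantity — it
reflects what was recorded during care, which over-represents conditions
that are routinely screened and under-represents those that are not, so it
should be read as a healthcare-consumption rate rather than a
general-population prevalence.

Assumptions worth stating explicitly:

* person ids uniquely identify patients (duplicate registrations inflate
  `N_P` and deflate prevalences);
* concept id 0 — the "no matching concept" sentinel — carries no
  information and is dropped on input with a tally;
* whatever domains appear in the three event tables are counted as-is.
  Real ETL pipelines leak `Device`, `Measurement`, `Observation` and
  similar domains into these tables; such concepts are counted like any
  other, with the caveat that their counts are only as complete as the
  tables they leaked from.

## Disclosure protection

Releasing exact small counts risks patient re-identification. The release
pipeline (`compute_dataset()`) therefore applies, in this fixed order:

1. **Iatrogenic-code removal.** Concepts matching a user-supplied
   two-column list of (vocabulary, code) pairs — codes describing
   complications of medical care — are removed from the single table and
   from every pair containing them, before anything is released. The list
   is resolved against the concept dictionary; codes that match nothing are
   reported and ignored.
2. **Rare-count exclusion.** Items with true count `<= min_count`
   (default 10) are dropped. The boundary is inclusive: a count of 10 is
   excluded, 11 survives.
3. **Poisson randomization.** Each surviving count is replaced by a single
   draw from a Poisson distribution with mean λ equal to the true count.
   The Poisson is the natural noise model for event counts and has the
   useful property that relative perturbation shrinks as counts grow
   (sd/mean = 1/√λ), so rare — more identifying — concepts are perturbed
   proportionally more.

Three consequences of randomizing singles and pairs independently are
documented rather than "fixed": a released pair count can exceed a released
single count, relative frequencies can exceed 1, and a randomized 2×2
table can have a negative derived cell, in which case the chi-square is
reported as unavailable instead of being silently clamped. Randomized
values at or below the exclusion threshold are retained: re-filtering after
randomization would truncate the released distribution and bias consumers'
estimates of small counts.

Draws are seeded per item as `hash(seed, dataset_id, concept key)` with a
small deterministic polynomial hash, making the release reproducible,
independent of row order, and independent across datasets and between the
single and pair tables of one dataset.

**Calibration.** `randomization_impact()` measures how often randomization
makes a released count statistically distinguishable from its true value,
using the simplest test consistent with a per-item comparison of two
counts: the df-1 Pearson goodness-of-fit statistic `(O − E)²/E` with `E`
the true count, no continuity correction, two-sided at `alpha`. Since a
Poisson(λ) draw has variance λ, the statistic is asymptotically χ²(1) and
the rejection rate converges to `alpha` from below as λ grows (discreteness
keeps it slightly under at small λ). `calibrate_randomization_impact()`
packages this as a simulation with true counts log-uniform over a released
count range; at 50,000 items and counts in [50, 10⁵] the measured rate sits
within Monte-Carlo noise of 5% at `alpha = 0.05`.

## Association measures

For a released pair with counts `(N_12, N_1, N_2, N_P)`:

* **Relative frequency** `FR(C1|C2) = N_12 / N_2` answers "among patients
  with `C2`, how many also have `C1`?". Ranked queries
  (`top_associated(..., metric = "relative_frequency")`) condition on the
  *partner*, so each row reads "among patients with the row's concept, this
  fraction also has the anchor" — the conditioning that makes a
  high-specificity partner rank above a merely popular one.
* **Log ratio** `LR = ln(N_12 N_P / (N_1 N_2))` compares the observed pair
  count to the count expected under independence. It is symmetric in the
  two concepts, zero at independence, and undefined at `N_12 = 0`
  (signalled as an error, not returned as −∞; zero pairs are anyway never
  released).
* **Chi-square** on the 2×2 table, df 1, without Yates correction: released
  expected counts are large, where the correction only biases the statistic
  downward. With the enormous `N_P` typical of EHR datasets the test is
  extremely sensitive, so statistical significance should not be read as
  clinical relevance — the log ratio is the effect-size companion.

Ranked queries operate on released (post-privacy) counts — the same tables
a public consumer sees; true-count mode exists in `compute_dataset()`'s
`true_singles`/`true_pairs` components for internal validation only. Ties
are broken by ascending concept id so all rankings are deterministic. No
multiple-testing correction is applied across pairs; queries are
exploratory rankings, not hypothesis tests.

## Annual stability statistics

To let consumers judge the temporal stability of a concept,
`annual_deviations()` treats each fully covered calendar year as its own
dataset with its own annual `N_P` and reports, per concept and pair:

* the **mean** over years of the *randomized* annual rate (the same
  protection as the released counts, applied per year with per-year seeds);
* the **standard deviation** over years of the *true* annual rates — the
  SD is a spread, already non-disclosive, and randomizing it would double
  the noise.

Years in which an item is absent contribute a rate of exactly 0; calendar
years with no events at all are skipped with a warning. Which years count
as "full" is a configuration input, not an inference — partial first/last
years of a database must not be passed. The SD convention is population SD
(divide by the number of years) because the years constitute the entire
period being described, not a sample from it; the sample convention is
available via `sd_type = "sample"`.

## Synthetic cohorts: what they emulate and what they do not

`generate_cohort()` draws, per patient, independent Bernoulli indicators
for each catalog concept at its specified marginal prevalence. For each
explicitly listed (disjoint) concept pair, the joint distribution is the
2×2 table determined by the two marginals and a target odds ratio ψ,
obtained from the quadratic identity
ψ·(p₁−p₁₁)(p₂−p₁₁) = p₁₁·(1−p₁−p₂+p₁₁), taking the root inside the
Fréchet bounds. Each positive patient–concept assignment emits
`1 + Poisson(events_per_positive − 1)` duplicate event rows with dates
uniform over the year window, so deduplication and window logic are
genuinely exercised. Demographics are categorical draws with an explicit
unmapped (id 0) remainder. Everything is deterministic given the seed.

Default demographics reflect a large urban hospital population: sex
recorded for essentially all patients at roughly 56%/44%, race and
ethnicity mostly unrecorded (over 80% unmapped) — missingness a consumer of
real EHR demographic prevalences must expect. The default
`events_per_positive = 2` makes duplicate rows common without bloating
tables.

Two subtleties matter when validating against the generator:

* **Inclusion selection.** `N_P` counts only patients with ≥ 1 clinical
  event, so prevalences *relative to N_P* exceed the generator's marginals,
  and conditioning on inclusion induces mild negative dependence among
  otherwise independent concepts (a Berkson-type effect). Parameter
  recovery is therefore checked against the generated patient total, where
  counts are unbiased; association checks use catalogs containing a
  high-prevalence concept so that nearly every patient is included and the
  effect is negligible — as in real EHR data, where essentially every
  patient has at least one recorded event.
* **What is *not* modeled.** No visit structure, disease trajectories,
  coding-system drift, within-patient temporal correlation, or concept
  hierarchy. Passing tests demonstrate the counting, privacy, and
  association machinery is correct — not that any clinical conclusion
  drawn from a real database is.

## Files and the query interface

The released flat files are tab-delimited with a header row: per dataset, a
single-concept file (`concept_id`, `count`, `prevalence`), a paired-concept
file (two ids, `count`, `prevalence`), and the two deviation files, plus a
shared `concepts.txt` with the six standard concept columns. All
frequencies are relative to 1.0. Frequencies are rendered with 6
significant digits by default (`digits = NA` gives full precision); row
order is canonical, so `write → read → write` round trips are
byte-identical. `N_P` appears in no canonical data file but is needed by
association queries, so the writer adds a small `dataset_metadata.txt`
(dataset id, patient count, window); a bundle read without it still serves
frequencies, just not associations.

The query layer (`bundle_api()` / `api_request()`) is an in-process,
stateless dispatcher over the released tables, mirroring a REST surface
(`/metadata/*`, `/omop/*`, `/frequencies/*`, `/association/*`) with JSON
serialization via `api_json()`. Every numeric payload equals the
corresponding library call exactly; the layer adds no computation. Two
deliberate behaviors: concept-mapping endpoints return a structured
"vocabulary not loaded" response unless a full vocabulary extract is
supplied, and a concept absent from the released tables yields *empty
results*, never zeros — absence due to privacy exclusion is
indistinguishable from true absence, and the interface must not pretend
otherwise.

## Numerical and edge-case choices

* `prevalence()` and friends guard their denominators (`N_P = 0`,
  `N_2 = 0` are errors, not `NaN`).
* Date parsing is strict `%Y-%m-%d` on the first 10 characters (datetimes
  lose their time part); impossible dates like Feb 30 are row-level errors
  under the default `fail` policy or tallied drops under `skip`.
* Concept names beyond the 255-character OMOP limit are an error unless
  truncation is requested.
* Window endpoints are inclusive on both sides.
* All ranking ties break by ascending concept id.

## A small demonstration

```{r demo}
wc <- worked_example_cohort()
pcm <- build_patient_concepts(cohort_events(wc), wc$person,
                              window = wc$window, dataset_id = "windowed")
pcm
count_singles(pcm)
head(count_pairs(pcm))
```

Ten generated patients; patient 9's only event predates the window and
patient 10 has no clinical events, so `N_P` is 8. Every count above is
hand-checkable, and the test suite checks all of them against a
brute-force enumeration written independently of the counting code.

## Problem sizes used in the test suite

Stochastic checks run at sizes chosen to make their tolerances meaningful:
parameter recovery at 10,000 patients (4 standard errors), brute-force
count equivalence at up to 200 patients and 15 concepts, Poisson moment
recovery at 20,000 draws, and impact calibration at 50,000 items in the
acceptance script. These are the scales at which the statistical
tolerances are tight enough to catch real defects while each check runs in
seconds.

## Known limitations

* No hierarchy-aware rollup (`concept_ancestor` is not consumed): a parent
  concept's count excludes its descendants.
* No temporal windows *between* concepts of a pair; a pair observed decades
  apart in a lifetime dataset still counts.
* The privacy pipeline is a pragmatic disclosure-protection scheme, not a
  formal differential-privacy mechanism; no privacy budget is accounted.
* Reading directly from a live SQL OMOP instance is out of scope; the
  readers consume delimited extracts.
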