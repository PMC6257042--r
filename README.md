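# omopfreq

Privacy-protected EHR concept prevalence and co-occurrence statistics from
OMOP Common Data Model extracts.

Clinical data warehouses can rarely share patient-level records, but they
*can* share aggregate statistics once disclosure risks are controlled.
`omopfreq` computes, from OMOP CDM v5-style table extracts
(`person`, `condition_occurrence`, `drug_exposure`, `procedure_occurrence`,
`concept`), the patient counts of every single concept and every concept
pair, applies a disclosure-protection pipeline, derives concept-association
measures, and publishes the results as tab-delimited flat files plus a JSON
query interface. A synthetic cohort generator with known statistical
structure makes the entire pipeline testable without any clinical data.

It is aimed at informatics groups who want to release (or consume) clinical
frequency statistics, and at researchers using such statistics for tasks
like drug-repurposing screens, pharmacovigilance, differential-diagnosis
support, or power estimation.

## The statistics

With `N_P` the number of unique patients having at least one condition,
drug, or procedure event in the dataset window, `N_C` the number of unique
patients observed with concept `C`, and `N_{C1,C2}` the number observed
with both members of a pair:

- **EHR prevalence**  `P_EHR(C) = N_C / N_P`
- **Co-occurrence frequency**  `CO_EHR(C1,C2) = N_{C1,C2} / N_P`
- **Relative frequency**  `FR(C1|C2) = N_{C1,C2} / N_{C2}` — an empirical
  analogue of the conditional probability of `C1` given `C2`
- **Observed-expected log ratio**
  `LR(C1,C2) = ln( N_{C1,C2} · N_P / (N_{C1} · N_{C2}) )` — positive when a
  pair co-occurs more often than independence predicts
- **Chi-square** — Pearson statistic (df 1, no continuity correction) on the
  2×2 patient contingency table of the pair

Counting is per *unique patient*: duplicate records of a concept for one
patient count once, and no temporal relation between the two concepts of a
pair is required. Demographic concepts (gender, race, ethnicity) join each
included patient's concept set but never by themselves qualify a patient
for inclusion.

Before release, three protections are applied in a fixed order:

1. **Iatrogenic-code removal** — concepts matching a supplied
   (vocabulary, code) list of complications-of-care codes are purged.
2. **Rare-count exclusion** — items with true count ≤ 10 are dropped.
3. **Poisson randomization** — every released count is replaced by one draw
   from a Poisson distribution with λ equal to the true count. Draws for
   singles and pairs are independent, so released relative frequencies can
   exceed 1; randomized values ≤ 10 are retained (re-filtering would bias
   the released distribution).

## Worked example

Generate a 10,000-patient synthetic cohort in which one condition–drug pair
(ids 3191 and 4401) is injected with odds ratio 6, release the 2013–2017
window, and query the associations:

```r
library(omopfreq)

catalog <- data.frame(
  concept_id = c(3191, 3192, 3193, 4401, 4402, 5501),
  domain     = c("Condition", "Condition", "Condition", "Drug", "Drug", "Procedure"),
  prevalence = c(0.13, 0.08, 0.40, 0.05, 0.10, 0.85)
)
spec <- cohort_spec(
  n_patients = 10000, concepts = catalog,
  dependence = data.frame(concept_id_1 = 3191, concept_id_2 = 4401, odds_ratio = 6),
  seed = 2026
)
cohort <- generate_cohort(spec)
events <- cohort_events(cohort)

released <- compute_dataset(
  events, cohort$person,
  window = as.Date(c("2013-01-01", "2017-12-31")),
  dataset_id = "5year",
  config = privacy_config(min_count = 10, seed = 42),
  full_years = 2013:2017
)
released$patient_count
#> [1] 9365
head(released$singles, 3)
#>    concept_id count prevalence
#> 1:       3191  1266 0.13518420
#> 2:       3192   794 0.08478377
#> 3:       3193  4077 0.43534437
```

`N_P` is 9365, not 10000: patients with no clinical event in the window are
excluded. The released counts are Poisson-randomized, which is why the
prevalence of concept 3191 (marginal 0.13 of all generated patients) reads
0.1352 of the included population.

```r
top_associated(3191, released$singles, released$pairs,
               n_p = released$patient_count, metric = "log_ratio",
               concepts = cohort$concept, domain = "Drug", k = 2)
#>    concept_id pair_count base_count relative_frequency  log_ratio        chi2
#> 1:       4401        211        472          0.4470339  1.1959962 413.4686757
#> 2:       4402        124        973          0.1274409 -0.0589855   0.5568739
```

The injected pair stands out: 211 patients share condition 3191 and drug
4401 against an expected 63.8 under independence (log ratio 1.196,
chi-square 413), while the independent drug 4402 sits at a log ratio near
0. Among patients on drug 4401, 44.7% carry the condition (`FR = 211/472`).

Release to disk and serve:

```r
bundle <- cohd_bundle(list(`5year` = released), cohort$concept)
write_bundle(bundle, "demo_bundle")
api <- bundle_api(read_bundle("demo_bundle"))
api_json(api_request(api, "/association/obsExpRatio",
                     list(concept_id_1 = 3191, concept_id_2 = 4401)))
#> {"status":200,"results":[{"dataset_id":"5year","concept_id_1":3191,
#>   "concept_id_2":4401,"observed_count":211,"expected_count":63.8069407367859,
#>   "ln_ratio":1.19599616006458}]}
```

A thin command-line front end over the same functions lives at
`inst/cli/omopfreq.R` (subcommands `generate`, `export`, `associate`,
`query`).

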