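test_that("single and pair counting match the brute-force oracle on random cohorts", {
  for (seed in c(1, 2, 3)) {
    cat <- data.frame(
      concept_id = seq(101L, length.out = 15L),
      domain = rep(c("Condition", "Drug", "Procedure"), 5),
      prevalence = runif(15, 0.02, 0.5)
    )
    ch <- generate_cohort(cohort_spec(150, cat, seed = seed))
    ev <- cohort_events(ch)
    pcm <- build_patient_concepts(ev, ch$person)
    sets <- oracle_patient_sets(ev, ch$person)
    expect_equal(pcm$n_patients, length(sets))
    expect_equal(as.data.frame(count_singles(pcm)[, .(concept_id, count)]),
                 oracle_single_counts(sets))
    expect_equal(as.data.frame(count_pairs(pcm)[, .(concept_id_1, concept_id_2, count)]),
                 oracle_pair_counts(sets))
  }
})

test_that("window boundaries are inclusive and demographics never qualify a patient", {
  persons <- data.table::data.table(person_id = 1:3,
                                    gender_concept_id = c(8507L, 8532L, 8507L),
                                    race_concept_id = 0L, ethnicity_concept_id = 0L)
  ev <- data.table::data.table(
    person_id = c(1L, 2L),
    concept_id = c(101L, 101L),
    event_date = as.Date(c("2012-12-31", "2013-01-01")),
    source_table = "condition"
  )
  win <- as.Date(c("2013-01-01", "2017-12-31"))
  pcm <- build_patient_concepts(ev, persons, window = win)
  # 2012-12-31 is outside, 2013-01-01 (the boundary) is inside
  expect_equal(pcm$n_patients, 1L)
  expect_equal(unique(pcm$concepts$person_id), 2L)
  # person 3 has a gender record but no clinical event: absent from map
  expect_false(3L %in% pcm$concepts$person_id)
  # boundary end date is inside too
  ev2 <- rbind(ev, data.table::data.table(person_id = 3L, concept_id = 102L,
                                          event_date = as.Date("2017-12-31"),
                                          source_table = "drug"))
  expect_equal(build_patient_concepts(ev2, persons, window = win)$n_patients, 2L)
})

test_that("shrinking the window never increases any count or N_P", {
  ch <- generate_cohort(cohort_spec(400, dense_catalog(), seed = 31))
  ev <- cohort_events(ch)
  wide <- build_patient_concepts(ev, ch$person,
                                 window = as.Date(c("2013-01-01", "2017-12-31")))
  narrow <- build_patient_concepts(ev, ch$person,
                                   window = as.Date(c("2014-01-01", "2016-12-31")))
  expect_lte(narrow$n_patients, wide$n_patients)
  sw <- count_singles(wide); sn <- count_singles(narrow)
  m <- merge(sw, sn, by = "concept_id", suffixes = c("_w", "_n"))
  expect_equal(nrow(m), nrow(sn)) # no concept appears only in the narrow window
  expect_true(all(m$count_n <= m$count_w))
  pw <- count_pairs(wide); pn <- count_pairs(narrow)
  mp <- merge(pw, pn, by = c("concept_id_1", "concept_id_2"),
              suffixes = c("_w", "_n"))
  expect_equal(nrow(mp), nrow(pn))
  expect_true(all(mp$count_n <= mp$count_w))
})

test_that("pair counts are bounded by their singles and frequencies are consistent", {
  ch <- generate_cohort(cohort_spec(500, dense_catalog(),
                                    dependence = data.frame(concept_id_1 = 11,
                                                            concept_id_2 = 13,
                                                            odds_ratio = 5),
                                    seed = 13))
  pcm <- build_patient_concepts(cohort_events(ch), ch$person)
  s <- count_singles(pcm)
  p <- count_pairs(pcm)
  m <- merge(p, s[, .(concept_id_1 = concept_id, n1 = count)], by = "concept_id_1")
  m <- merge(m, s[, .(concept_id_2 = concept_id, n2 = count)], by = "concept_id_2")
  expect_true(all(m$count <= pmin(m$n1, m$n2)))
  expect_true(all(p$prevalence <= 1))
  expect_true(all(abs(s$prevalence - s$count / pcm$n_patients) < 1e-15))
  # canonical order, stored once, no self pairs
  expect_true(all(p$concept_id_1 < p$concept_id_2))
  expect_equal(anyDuplicated(p, by = c("concept_id_1", "concept_id_2")), 0L)
})

test_that("prevalence is exact division with guarded denominator", {
  expect_equal(prevalence(233790, 1790431), 233790 / 1790431)
  expect_equal(prevalence(5, 5), 1)
  expect_equal(cooccurrence_frequency(3, 12), 0.25)
  expect_error(prevalence(1, 0), class = "omopfreq_value_error")
  expect_error(prevalence(-1, 10), class = "omopfreq_value_error")
})

test_that("annual deviations follow the randomized-mean / true-sd convention", {
  # 3 full years, N_P = 100 each, concept 5 with true counts 20/30/40
  persons <- data.table::data.table(person_id = 1:100,
                                    gender_concept_id = 0L,
                                    race_concept_id = 0L,
                                    ethnicity_concept_id = 0L)
  filler <- data.table::CJ(person_id = 1:100, year = 2014:2016)
  filler <- data.table::data.table(person_id = filler$person_id,
                                   concept_id = 999L,
                                   event_date = as.Date(sprintf("%d-06-01", filler$year)),
                                   source_table = "condition")
  conc5 <- data.table::rbindlist(list(
    data.table::data.table(person_id = 1:20, concept_id = 5L,
                           event_date = as.Date("2014-02-01"), source_table = "condition"),
    data.table::data.table(person_id = 1:30, concept_id = 5L,
                           event_date = as.Date("2015-02-01"), source_table = "condition"),
    data.table::data.table(person_id = 1:40, concept_id = 5L,
                           event_date = as.Date("2016-02-01"), source_table = "condition")
  ))
  ev <- rbind(filler, conc5)

  dev <- annual_deviations(ev, persons, full_years = 2014:2016, seed = 4,
                           include_pairs = FALSE)
  rates <- c(0.2, 0.3, 0.4)
  # population sd of the true annual rates, computed directly
  expect_equal(dev$singles[concept_id == 5L, sd_rate],
               sqrt(mean((rates - mean(rates))^2)))
  # sample-sd convention is configurable
  dev_s <- annual_deviations(ev, persons, full_years = 2014:2016, seed = 4,
                             sd_type = "sample", include_pairs = FALSE)
  expect_equal(dev_s$singles[concept_id == 5L, sd_rate], sd(rates))
  # mean uses randomized counts: equals mean of the actual per-year draws
  draws <- vapply(2014:2016, function(y) {
    tab <- data.table::data.table(
      concept_id = 5L,
      count = c(`2014` = 20L, `2015` = 30L, `2016` = 40L)[as.character(y)]
    )
    poisson_randomize(tab, seed = 4, dataset_id = sprintf("year-%d", y))$count
  }, integer(1))
  expect_equal(dev$singles[concept_id == 5L, mean_rate], mean(draws / 100))

  # constant series: sd exactly 0, mean near the rate within Poisson noise
  expect_equal(dev$singles[concept_id == 999L, sd_rate], 0)
  expect_lt(abs(dev$singles[concept_id == 999L, mean_rate] - 1), 0.15)

  # an empty year is skipped with a warning
  expect_warning(
    dev2 <- annual_deviations(ev, persons, full_years = 2013:2016, seed = 4,
                              include_pairs = FALSE),
    "no clinical events"
  )
  expect_equal(dev2$years_used, 2014:2016)
})
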