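fixture_api <- function() {
  wc <- worked_example_cohort()
  ev <- cohort_events(wc)
  # no exclusion or randomization: tiny fixture served in true-count mode so
  # endpoint payloads can be checked against library calls exactly
  pcm5 <- build_patient_concepts(ev, wc$person, window = wc$window,
                                 dataset_id = "5year")
  pcml <- build_patient_concepts(ev, wc$person, dataset_id = "lifetime")
  b <- cohd_bundle(list(
    `5year` = list(singles = count_singles(pcm5), pairs = count_pairs(pcm5),
                   patient_count = pcm5$n_patients, window = wc$window),
    lifetime = list(singles = count_singles(pcml), pairs = count_pairs(pcml),
                    patient_count = pcml$n_patients, window = NULL)
  ), wc$concept)
  bundle_api(b)
}

test_that("metadata endpoints expose datasets, domain tallies, and N_P", {
  api <- fixture_api()
  r <- api_request(api, "/metadata/datasets")
  expect_equal(r$status, 200L)
  expect_length(r$results, 2L)
  expect_equal(vapply(r$results, `[[`, character(1), "dataset_id"),
               c("5year", "lifetime"))

  r <- api_request(api, "/metadata/patientCount", list(dataset_id = "5year"))
  expect_equal(r$results[[1]]$patient_count, 8L)
  expect_equal(api_request(api, "/metadata/patientCount",
                           list(dataset_id = "lifetime"))$results[[1]]$patient_count, 9L)

  # domain tallies equal a brute-force group-by over singles x concepts
  r <- api_request(api, "/metadata/domainCounts", list(dataset_id = "5year"))
  got <- setNames(vapply(r$results, `[[`, integer(1), "count"),
                  vapply(r$results, `[[`, character(1), "domain_id"))
  s <- api$bundle$datasets$`5year`$singles
  cd <- as.data.frame(api$bundle$concepts)
  want <- table(cd$domain_id[match(s$concept_id, cd$concept_id)])
  expect_equal(got[sort(names(want))], unlist(as.list(want))[sort(names(want))],
               ignore_attr = TRUE)

  r <- api_request(api, "/metadata/domainPairCounts", list(dataset_id = "5year"))
  total <- sum(vapply(r$results, `[[`, integer(1), "count"))
  expect_equal(total, nrow(api$bundle$datasets$`5year`$pairs))
  # unknown dataset -> 4xx record
  r <- api_request(api, "/metadata/patientCount", list(dataset_id = "nope"))
  expect_equal(r$status, 404L)
})

test_that("concept search matches case-insensitive substrings with deterministic ranking", {
  api <- fixture_api()
  r <- api_request(api, "/omop/findConceptIDs", list(q = "hypertension"))
  expect_equal(r$results[[1]]$concept_id, 101L)
  r <- api_request(api, "/omop/findConceptIDs", list(q = "ZZZ-nothing"))
  expect_equal(r$status, 200L)
  expect_length(r$results, 0L)
  # domain filter excludes non-matching domains
  r <- api_request(api, "/omop/findConceptIDs",
                   list(q = "synthetic", domain = "Drug"))
  expect_true(all(vapply(r$results, `[[`, character(1), "domain_id") == "Drug"))
  expect_equal(api_request(api, "/omop/findConceptIDs", list(q = ""))$status, 400L)
  # definition lookup and vocabulary endpoints
  r <- api_request(api, "/omop/concepts", list(q = 101L))
  expect_equal(r$results[[1]]$concept_name, "Synthetic hypertension")
  expect_equal(api_request(api, "/omop/vocabularies")$status, 501L)
  expect_match(api_request(api, "/omop/mapToStandardConceptID")$error,
               "vocabulary not loaded")
})

test_that("frequency endpoints are thin views over the library functions", {
  api <- fixture_api()
  d <- api$bundle$datasets$`5year`
  r <- api_request(api, "/frequencies/singleConceptFreq",
                   list(dataset_id = "5year", q = 101L))
  expect_equal(r$results[[1]]$count, d$singles[concept_id == 101L, count])
  expect_equal(r$results[[1]]$prevalence, d$singles[concept_id == 101L, prevalence])
  # a concept absent from the released table returns empty results, not zeros
  r <- api_request(api, "/frequencies/singleConceptFreq",
                   list(dataset_id = "5year", q = 424242L))
  expect_equal(r$status, 200L)
  expect_length(r$results, 0L)

  r <- api_request(api, "/frequencies/pairedConceptFreq",
                   list(dataset_id = "5year", concept_id_1 = 102L,
                        concept_id_2 = 101L))
  expect_equal(r$results[[1]]$count,
               d$pairs[concept_id_1 == 101L & concept_id_2 == 102L, count])
  # never co-occurring pair -> empty
  r <- api_request(api, "/frequencies/pairedConceptFreq",
                   list(dataset_id = "5year", concept_id_1 = 103L,
                        concept_id_2 = 201L))
  expect_length(r$results, 0L)

  r <- api_request(api, "/frequencies/mostFrequentConcepts",
                   list(dataset_id = "5year", k = 3L, domain = "Condition"))
  ref <- most_frequent(d$singles, api$bundle$concepts, domain = "Condition", k = 3L)
  expect_equal(vapply(r$results, `[[`, integer(1), "concept_id"), ref$concept_id)

  r <- api_request(api, "/frequencies/associatedConceptDomainFreq",
                   list(dataset_id = "5year", concept_id = 102L,
                        domain = "Drug", k = 5L))
  ref <- top_associated(102L, d$singles, d$pairs, n_p = d$patient_count,
                        metric = "count", concepts = api$bundle$concepts,
                        domain = "Drug", k = 5L)
  expect_equal(vapply(r$results, `[[`, integer(1), "concept_id"), ref$concept_id)
  expect_equal(vapply(r$results, `[[`, integer(1), "pair_count"), ref$pair_count)
})

test_that("association endpoints delegate exactly and report structured errors", {
  api <- fixture_api()
  d <- api$bundle$datasets$`5year`
  n_p <- d$patient_count
  n1 <- d$singles[concept_id == 101L, count]
  n2 <- d$singles[concept_id == 102L, count]
  n12 <- d$pairs[concept_id_1 == 101L & concept_id_2 == 102L, count]

  r <- api_request(api, "/association/chiSquare",
                   list(dataset_id = "5year", concept_id_1 = 101L,
                        concept_id_2 = 102L))
  ref <- chi_square_pair(n12, n1, n2, n_p)
  expect_equal(r$results[[1]]$chi_square, ref$chi2)
  expect_equal(r$results[[1]]$p_value, ref$p_value)

  r <- api_request(api, "/association/obsExpRatio",
                   list(dataset_id = "5year", concept_id_1 = 101L,
                        concept_id_2 = 102L))
  expect_equal(r$results[[1]]$observed_count, n12)
  expect_equal(r$results[[1]]$expected_count, expected_count(n1, n2, n_p))
  expect_equal(r$results[[1]]$ln_ratio, log_ratio(n12, n1, n2, n_p))

  r <- api_request(api, "/association/relativeFrequency",
                   list(dataset_id = "5year", concept_id_1 = 101L,
                        concept_id_2 = 102L))
  expect_equal(r$results[[1]]$relative_frequency, relative_frequency(n12, n2))
  expect_equal(r$results[[1]]$concept_2_count, n2)

  # randomized counts can make a 2x2 cell negative: structured error payload
  singles <- data.table::data.table(concept_id = c(1L, 2L),
                                    count = c(12L, 14L),
                                    prevalence = c(0.12, 0.14))
  pairs <- data.table::data.table(concept_id_1 = 1L, concept_id_2 = 2L,
                                  count = 20L, prevalence = 0.2)
  api2 <- bundle_api(cohd_bundle(
    list(demo = list(singles = singles, pairs = pairs,
                     patient_count = 100L, window = NULL)),
    concepts = demo_concepts <- data.table::data.table(
      concept_id = 1:2, concept_name = c("a", "b"), domain_id = "Condition",
      vocabulary_id = "SNOMED", concept_class_id = "x",
      concept_code = c("1", "2"))
  ))
  r <- api_request(api2, "/association/chiSquare",
                   list(concept_id_1 = 1L, concept_id_2 = 2L))
  expect_equal(r$status, 422L)
  expect_match(r$error, "negative")

  # unknown endpoint is a structured 404
  expect_equal(api_request(api, "/nope")$status, 404L)
  # responses serialize to JSON
  expect_match(as.character(api_json(api_request(api, "/metadata/datasets"))),
               "\"dataset_id\":\"5year\"", fixed = TRUE)
})
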