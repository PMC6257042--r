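## Synthetic OMOP cohort generator.
##
## Patients carry independent Bernoulli indicators for each catalog concept,
## except for explicitly listed disjoint concept pairs whose joint presence
## follows the 2x2 distribution determined by the two marginal prevalences
## and a specified odds ratio. Positive patient-concept assignments emit one
## or more duplicate event rows with dates uniform over the year window, so
## the generated tables exercise de-duplication and date-window logic
## downstream.

#' Specify a synthetic cohort
#'
#' @param n_patients number of patients.
#' @param concepts data.frame with columns `concept_id`, `domain`
#'   (`Condition`, `Drug`, `Procedure`, or another OMOP domain), and
#'   `prevalence` (marginal probability in `[0, 1]` that a patient carries
#'   the concept).
#' @param year_range inclusive calendar-year interval `c(first, last)` over
#'   which event dates are drawn uniformly.
#' @param dependence optional data.frame with columns `concept_id_1`,
#'   `concept_id_2`, `odds_ratio` (> 0) injecting pairwise dependence
#'   between catalog concepts. Pairs must be disjoint (no concept may
#'   appear in two pairs).
#' @param demographics named list with optional elements `gender`, `race`,
#'   `ethnicity`; each a named numeric vector mapping concept ids to
#'   probabilities summing to at most 1 (the remainder is unmapped, id 0).
#'   Defaults reflect a large urban hospital population: sex recorded for
#'   essentially all patients, race/ethnicity mostly unrecorded.
#' @param events_per_positive mean number of event rows per positive
#'   patient-concept assignment (>= 1); rows beyond the first are
#'   `rpois(events_per_positive - 1)`.
#' @param seed integer seed; generation is fully deterministic given the
#'   spec.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients,
                        concepts,
                        year_range = c(2013L, 2017L),
                        dependence = NULL,
                        demographics = list(
                          gender = c("8507" = 0.440, "8532" = 0.557),
                          race = c("8527" = 0.10, "8516" = 0.07),
                          ethnicity = c("38003563" = 0.055, "38003564" = 0.105)
                        ),
                        events_per_positive = 2,
                        seed = 1L) {
  stopifnot(n_patients >= 1, length(year_range) == 2L,
            year_range[1] <= year_range[2], events_per_positive >= 1)
  concepts <- data.table::as.data.table(concepts)
  check_columns(concepts, c("concept_id", "domain", "prevalence"), "concepts")
  if (any(concepts$prevalence < 0 | concepts$prevalence > 1)) {
    stop_value("marginal prevalences must lie in [0, 1]")
  }
  if (anyDuplicated(concepts$concept_id)) {
    stop_integrity("duplicate concept_id in concept catalog")
  }
  if (!is.null(dependence)) {
    dependence <- data.table::as.data.table(dependence)
    check_columns(dependence, c("concept_id_1", "concept_id_2", "odds_ratio"),
                  "dependence")
    if (any(dependence$odds_ratio <= 0)) stop_value("odds ratios must be > 0")
    ids <- c(dependence$concept_id_1, dependence$concept_id_2)
    if (anyDuplicated(ids)) {
      stop_value("dependence pairs must be disjoint; concept %d appears in more than one pair",
                 ids[duplicated(ids)][1L])
    }
    if (!all(ids %in% concepts$concept_id)) {
      stop_value("dependence pair references a concept missing from the catalog")
    }
  }
  for (dem in names(demographics)) {
    p <- demographics[[dem]]
    if (length(p) > 0 && (any(p < 0) || sum(p) > 1 + 1e-12)) {
      stop_value("demographic probabilities for '%s' must be non-negative and sum to <= 1", dem)
    }
  }
  structure(list(n_patients = as.integer(n_patients),
                 concepts = concepts,
                 year_range = as.integer(year_range),
                 dependence = dependence,
                 demographics = demographics,
                 events_per_positive = events_per_positive,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

## Joint probability p11 of a 2x2 table with marginals (p1, p2) and odds
## ratio `or`, via the standard quadratic identity
##   or = p11 * (1 - p1 - p2 + p11) / ((p1 - p11) * (p2 - p11)).
## Both quadratic roots are evaluated and the one inside the Frechet bounds
## is returned.
joint_cell_from_or <- function(p1, p2, or) {
  lo <- max(0, p1 + p2 - 1)
  hi <- min(p1, p2)
  if (abs(or - 1) < 1e-12) {
    p11 <- p1 * p2
  } else {
    s <- 1 + (p1 + p2) * (or - 1)
    disc <- s^2 - 4 * or * (or - 1) * p1 * p2
    if (disc < 0) return(NA_real_)
    roots <- (s + c(-1, 1) * sqrt(disc)) / (2 * (or - 1))
    ok <- roots >= lo - 1e-12 & roots <= hi + 1e-12
    if (!any(ok)) return(NA_real_)
    p11 <- min(max(roots[ok][1L], lo), hi)
  }
  if (p11 < lo - 1e-12 || p11 > hi + 1e-12) return(NA_real_)
  p11
}

#' Generate a synthetic OMOP-shaped cohort
#'
#' Produces five in-memory tables (`person`, `condition_occurrence`,
#' `drug_exposure`, `procedure_occurrence`, `concept`) with the column
#' names expected by [read_persons()], [read_events()], and
#' [read_concepts()]. Concepts whose domain is not `Condition`, `Drug`, or
#' `Procedure` are routed into the condition table, emulating the domain
#' leakage real ETL pipelines exhibit.
#'
#' @param spec a [cohort_spec()].
#' @return a named list of `data.table`s plus the generation `spec`, with
#'   class `omop_cohort`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  cat <- spec$concepts

  ## concept membership matrix: patients x catalog concepts
  member <- matrix(FALSE, nrow = n, ncol = nrow(cat),
                   dimnames = list(NULL, as.character(cat$concept_id)))
  dep_ids <- integer()
  if (!is.null(spec$dependence) && nrow(spec$dependence) > 0) {
    for (i in seq_len(nrow(spec$dependence))) {
      d <- spec$dependence[i]
      p1 <- cat[concept_id == d$concept_id_1, prevalence]
      p2 <- cat[concept_id == d$concept_id_2, prevalence]
      p11 <- joint_cell_from_or(p1, p2, d$odds_ratio)
      if (is.na(p11)) {
        stop_value("infeasible (marginal, odds ratio) combination for pair (%d, %d)",
                   d$concept_id_1, d$concept_id_2)
      }
      probs <- c(p11, p1 - p11, p2 - p11, 1 - p1 - p2 + p11)
      probs <- pmax(probs, 0)
      cell <- sample.int(4L, n, replace = TRUE, prob = probs)
      member[, as.character(d$concept_id_1)] <- cell %in% c(1L, 2L)
      member[, as.character(d$concept_id_2)] <- cell %in% c(1L, 3L)
      dep_ids <- c(dep_ids, d$concept_id_1, d$concept_id_2)
    }
  }
  indep <- setdiff(cat$concept_id, dep_ids)
  for (cid in indep) {
    p <- cat[concept_id == cid, prevalence]
    member[, as.character(cid)] <- rbinom(n, 1L, p) == 1L
  }

  ## demographics
  draw_dem <- function(p) {
    if (is.null(p) || length(p) == 0L) return(rep(0L, n))
    ids <- c(as.integer(names(p)), 0L)
    probs <- c(unname(p), max(0, 1 - sum(p)))
    ids[sample.int(length(ids), n, replace = TRUE, prob = probs)]
  }
  person <- data.table::data.table(
    person_id = seq_len(n),
    gender_concept_id = draw_dem(spec$demographics$gender),
    race_concept_id = draw_dem(spec$demographics$race),
    ethnicity_concept_id = draw_dem(spec$demographics$ethnicity)
  )

  ## event rows: >= 1 per positive assignment, dates uniform over window
  day0 <- as.Date(sprintf("%d-01-01", spec$year_range[1]))
  day1 <- as.Date(sprintf("%d-12-31", spec$year_range[2]))
  n_days <- as.integer(day1 - day0) + 1L
  pos <- which(member, arr.ind = TRUE)
  ev <- data.table::data.table(
    person_id = pos[, 1L],
    concept_id = cat$concept_id[pos[, 2L]]
  )
  data.table::setorder(ev, person_id, concept_id)
  reps <- 1L + rpois(nrow(ev), spec$events_per_positive - 1)
  ev <- ev[rep(seq_len(nrow(ev)), reps)]
  ev[, event_date := day0 + (sample.int(n_days, nrow(ev), replace = TRUE) - 1L)]
  ev <- merge(ev, cat[, .(concept_id, domain)], by = "concept_id", sort = FALSE)

  route <- function(domains) ev[domain %in% domains]
  cond <- route(setdiff(unique(cat$domain), c("Drug", "Procedure")))
  drug <- route("Drug")
  proc <- route("Procedure")

  mk_table <- function(e, id_name, id_col, date_col) {
    out <- data.table::data.table(
      id = seq_len(nrow(e)),
      person_id = e$person_id,
      concept_id = e$concept_id,
      event_date = e$event_date
    )
    data.table::setnames(out, c(id_name, "person_id", id_col, date_col))
    out
  }
  condition_occurrence <- mk_table(cond, "condition_occurrence_id",
                                   "condition_concept_id", "condition_start_date")
  drug_exposure <- mk_table(drug, "drug_exposure_id",
                            "drug_concept_id", "drug_exposure_start_date")
  procedure_occurrence <- mk_table(proc, "procedure_occurrence_id",
                                   "procedure_concept_id", "procedure_date")

  concept <- rbind(
    cat[, .(concept_id,
            concept_name = sprintf("Synthetic %s %d", tolower(domain), concept_id),
            domain_id = domain,
            vocabulary_id = data.table::fcase(domain == "Drug", "RxNorm",
                                              domain == "Procedure", "CPT4",
                                              default = "SNOMED"),
            concept_class_id = data.table::fcase(domain == "Drug", "Clinical Drug",
                                                 domain == "Procedure", "Procedure",
                                                 default = "Clinical Finding"),
            concept_code = as.character(concept_id))],
    demographic_concepts()
  )
  concept <- concept[concept_id %in% c(cat$concept_id,
                                       person$gender_concept_id,
                                       person$race_concept_id,
                                       person$ethnicity_concept_id)]
  data.table::setkey(concept, concept_id)

  structure(list(person = person,
                 condition_occurrence = condition_occurrence,
                 drug_exposure = drug_exposure,
                 procedure_occurrence = procedure_occurrence,
                 concept = concept,
                 spec = spec),
            class = "omop_cohort")
}

## Standard OMOP demographic concept rows used by the generator and the
## worked example.
demographic_concepts <- function() {
  data.table::data.table(
    concept_id = c(8507L, 8532L, 8527L, 8516L, 38003563L, 38003564L),
    concept_name = c("MALE", "FEMALE", "White", "Black or African American",
                     "Hispanic or Latino", "Not Hispanic or Latino"),
    domain_id = c("Gender", "Gender", "Race", "Race", "Ethnicity", "Ethnicity"),
    vocabulary_id = c("Gender", "Gender", "Race", "Race", "Ethnicity", "Ethnicity"),
    concept_class_id = c("Gender", "Gender", "Race", "Race", "Ethnicity", "Ethnicity"),
    concept_code = c("M", "F", "5", "3", "Hispanic", "Not Hispanic")
  )
}

#' A tiny fixed cohort with hand-enumerable counts
#'
#' Ten patients, five clinical concepts, fixed event dates. The cohort
#' covers the edge cases that matter for counting: duplicate event rows for
#' one patient-concept (patient 1), a patient whose only event falls before
#' the 2013--2017 window (patient 9), and a patient with demographics but no
#' clinical events (patient 10, never counted). Every single and paired
#' count is small enough to enumerate by hand or brute force.
#'
#' @return a list with the five OMOP-shaped tables and `window`, the
#'   `Date` interval `2013-01-01 .. 2017-12-31` of the windowed dataset.
#' @export
worked_example_cohort <- function() {
  person <- data.table::data.table(
    person_id = 1:10,
    gender_concept_id = c(8507L, 8532L, 8507L, 8532L, 8507L,
                          8532L, 8507L, 8532L, 8507L, 8532L),
    race_concept_id = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 8527L, 0L, 0L),
    ethnicity_concept_id = rep(0L, 10)
  )
  cond <- data.table::data.table(
    condition_occurrence_id = 1:10,
    person_id = c(1L, 1L, 1L, 2L, 3L, 3L, 4L, 5L, 6L, 9L),
    condition_concept_id = c(101L, 101L, 102L, 101L, 101L, 102L,
                             102L, 103L, 101L, 101L),
    condition_start_date = as.Date(c("2014-03-01", "2014-06-15", "2015-02-10",
                                     "2013-05-20", "2017-08-08", "2014-01-30",
                                     "2016-11-11", "2015-04-04", "2016-02-29",
                                     "2012-12-31"))
  )
  cond2 <- data.table::data.table(
    condition_occurrence_id = 11L, person_id = 6L,
    condition_concept_id = 103L,
    condition_start_date = as.Date("2014-09-09")
  )
  cond <- rbind(cond, cond2)
  drug <- data.table::data.table(
    drug_exposure_id = 1:4,
    person_id = c(1L, 2L, 4L, 7L),
    drug_concept_id = rep(201L, 4),
    drug_exposure_start_date = as.Date(c("2015-02-11", "2016-07-01",
                                         "2013-03-03", "2014-10-10"))
  )
  proc <- data.table::data.table(
    procedure_occurrence_id = 1:3,
    person_id = c(3L, 6L, 8L),
    procedure_concept_id = rep(301L, 3),
    procedure_date = as.Date(c("2014-01-31", "2015-06-06", "2016-12-12"))
  )
  concept <- rbind(
    data.table::data.table(
      concept_id = c(101L, 102L, 103L, 201L, 301L),
      concept_name = c("Synthetic hypertension", "Synthetic atrial fibrillation",
                       "Synthetic cough", "Synthetic anticoagulant",
                       "Synthetic electrocardiogram"),
      domain_id = c("Condition", "Condition", "Condition", "Drug", "Procedure"),
      vocabulary_id = c("SNOMED", "SNOMED", "SNOMED", "RxNorm", "CPT4"),
      concept_class_id = c("Clinical Finding", "Clinical Finding",
                           "Clinical Finding", "Clinical Drug", "Procedure"),
      concept_code = c("101", "102", "103", "201", "301")
    ),
    demographic_concepts()
  )
  data.table::setkey(concept, concept_id)
  list(person = person,
       condition_occurrence = cond,
       drug_exposure = drug,
       procedure_occurrence = proc,
       concept = concept,
       window = as.Date(c("2013-01-01", "2017-12-31")))
}

#' Normalize an OMOP cohort's event tables into one event stream
#'
#' Stacks the three event tables of a cohort into the normalized
#' `(person_id, concept_id, event_date, source_table)` shape produced by
#' [read_events()], dropping rows with concept id 0.
#'
#' @param cohort a list with `condition_occurrence`, `drug_exposure`,
#'   `procedure_occurrence` tables (e.g. from [generate_cohort()] or
#'   [worked_example_cohort()]).
#' @return a `data.table` of clinical events.
#' @export
cohort_events <- function(cohort) {
  pick <- function(tb, id_col, date_col, label) {
    if (is.null(tb) || nrow(tb) == 0L) {
      return(data.table::data.table(person_id = integer(),
                                    concept_id = integer(),
                                    event_date = as.Date(character()),
                                    source_table = character()))
    }
    data.table::data.table(person_id = as.integer(tb$person_id),
                           concept_id = as.integer(tb[[id_col]]),
                           event_date = as.Date(tb[[date_col]]),
                           source_table = label)
  }
  ev <- rbind(
    pick(cohort$condition_occurrence, "condition_concept_id",
         "condition_start_date", "condition"),
    pick(cohort$drug_exposure, "drug_concept_id",
         "drug_exposure_start_date", "drug"),
    pick(cohort$procedure_occurrence, "procedure_concept_id",
         "procedure_date", "procedure")
  )
  ev[concept_id != 0L]
}
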