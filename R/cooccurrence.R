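## Patient-level concept sets and true single / paired counts.
##
## EHR prevalence of a concept C is P_EHR(C) = N_C / N_P where N_C is the
## number of unique patients observed with C in the dataset window and N_P
## the number of unique patients with at least one clinical event in the
## window. Co-occurrence frequency of a pair is CO_EHR = N_{C1,C2} / N_P,
## the fraction of patients observed with both concepts anywhere in the
## window (no temporal relation between the two events is required).

#' Build per-patient concept sets for a dataset window
#'
#' Deduplicates clinical events to unique (patient, concept) pairs within
#' the (inclusive) date window, then adds each included patient's non-zero
#' demographic concept ids (gender, race, ethnicity). A patient is included
#' only if at least one condition, drug, or procedure event falls in the
#' window; demographics alone never qualify a patient.
#'
#' @param events event table from [read_events()] / [cohort_events()]
#'   (rbind several source tables to combine them).
#' @param persons person table from [read_persons()].
#' @param window optional `Date` vector `c(start, end)`, inclusive; `NULL`
#'   means no date restriction ("lifetime").
#' @param dataset_id label attached to downstream tables.
#' @return an object of class `patient_concepts`: a list with `concepts`
#'   (a `data.table` of unique `person_id`, `concept_id` rows),
#'   `n_patients` (N_P), `dataset_id`, and `window`.
#' @export
build_patient_concepts <- function(events, persons, window = NULL,
                                   dataset_id = "dataset") {
  ev <- data.table::as.data.table(events)
  if (!is.null(window)) {
    window <- as.Date(window)
    stopifnot(length(window) == 2L, window[1] <= window[2])
    ev <- ev[event_date >= window[1] & event_date <= window[2]]
  }
  clin <- unique(ev[concept_id != 0L, .(person_id, concept_id)])
  included <- unique(clin$person_id)

  dem <- data.table::as.data.table(persons)[person_id %in% included]
  dem_long <- data.table::rbindlist(list(
    dem[, .(person_id, concept_id = gender_concept_id)],
    dem[, .(person_id, concept_id = race_concept_id)],
    dem[, .(person_id, concept_id = ethnicity_concept_id)]
  ))[concept_id != 0L]

  map <- unique(rbind(clin, dem_long))
  data.table::setkey(map, person_id, concept_id)
  structure(list(concepts = map,
                 n_patients = length(included),
                 dataset_id = dataset_id,
                 window = window),
            class = "patient_concepts")
}

#' @export
print.patient_concepts <- function(x, ...) {
  win <- if (is.null(x$window)) "lifetime" else paste(x$window, collapse = " .. ")
  cat(sprintf("<patient_concepts '%s'> %d patients, %d concepts, window %s\n",
              x$dataset_id, x$n_patients,
              data.table::uniqueN(x$concepts$concept_id), win))
  invisible(x)
}

#' True single-concept patient counts and EHR prevalence
#'
#' @param pcm a `patient_concepts` object.
#' @return a `data.table` with columns `concept_id`, `count`, `prevalence`
#'   ordered by `concept_id`. Attribute `n_patients` carries N_P and
#'   `dataset_id` the dataset label.
#' @export
count_singles <- function(pcm) {
  stopifnot(inherits(pcm, "patient_concepts"))
  out <- pcm$concepts[, .(count = data.table::uniqueN(person_id)), by = concept_id]
  out[, prevalence := count / pcm$n_patients]
  data.table::setorder(out, concept_id)
  data.table::setattr(out, "n_patients", pcm$n_patients)
  data.table::setattr(out, "dataset_id", pcm$dataset_id)
  out[]
}

#' True paired-concept patient counts and co-occurrence frequency
#'
#' Counts, for every unordered pair of concepts observed together in at
#' least one patient, the number of unique patients carrying both. Pairs
#' are stored once in canonical order `concept_id_1 < concept_id_2`;
#' self-pairs are not emitted.
#'
#' @param pcm a `patient_concepts` object.
#' @return a `data.table` with columns `concept_id_1`, `concept_id_2`,
#'   `count`, `prevalence`, ordered by the id pair, with attributes as in
#'   [count_singles()].
#' @export
count_pairs <- function(pcm) {
  stopifnot(inherits(pcm, "patient_concepts"))
  dt <- pcm$concepts
  joined <- merge(dt, dt, by = "person_id", allow.cartesian = TRUE,
                  suffixes = c("_1", "_2"))
  joined <- joined[concept_id_1 < concept_id_2]
  out <- joined[, .(count = .N), by = .(concept_id_1, concept_id_2)]
  out[, prevalence := count / pcm$n_patients]
  data.table::setorder(out, concept_id_1, concept_id_2)
  data.table::setattr(out, "n_patients", pcm$n_patients)
  data.table::setattr(out, "dataset_id", pcm$dataset_id)
  out[]
}

#' EHR prevalence / co-occurrence frequency from counts
#'
#' `prevalence()` computes N_C / N_P; `cooccurrence_frequency()` is the
#' same arithmetic for a pair count. True counts give values in `(0, 1]`;
#' Poisson-randomized counts may exceed N_C bounds.
#'
#' @param n_c patient count (vectorized).
#' @param n_p dataset patient count N_P (> 0).
#' @return numeric frequency, no internal rounding.
#' @export
prevalence <- function(n_c, n_p) {
  if (length(n_p) != 1L || is.na(n_p) || n_p <= 0) {
    stop_value("N_P must be a single positive patient count")
  }
  if (any(n_c < 0)) stop_value("patient counts must be non-negative")
  n_c / n_p
}

#' @rdname prevalence
#' @param n12 pair patient count.
#' @export
cooccurrence_frequency <- function(n12, n_p) prevalence(n12, n_p)

#' Annual stability statistics for singles and pairs
#'
#' For each calendar year in `full_years`, the year is treated as its own
#' dataset window with its own annual N_P. The mean annual rate is computed
#' from Poisson-randomized annual counts (the same disclosure protection
#' applied to the released datasets); the standard deviation is computed
#' from the true annual rates. Years in which a concept (or pair) has no
#' patients contribute a rate of 0; years with no events at all are
#' skipped with a warning.
#'
#' @param events,persons as in [build_patient_concepts()].
#' @param full_years integer vector of calendar years fully covered by the
#'   data (partial years must not be passed).
#' @param seed master randomization seed.
#' @param sd_type `"population"` (divide by the number of years, default)
#'   or `"sample"` (n - 1).
#' @param include_pairs compute pair deviations too (quadratic in concept
#'   set sizes; disable for singles-only use).
#' @return a list with `singles` and `pairs` `data.table`s
#'   (`mean_rate`, `sd_rate` per concept or canonical pair) and
#'   `years_used`.
#' @export
annual_deviations <- function(events, persons, full_years, seed = 0L,
                              sd_type = c("population", "sample"),
                              include_pairs = TRUE) {
  sd_type <- match.arg(sd_type)
  stopifnot(length(full_years) >= 1L)
  full_years <- sort(as.integer(full_years))

  singles_rates <- list()
  pairs_rates <- list()
  years_used <- integer()
  for (y in full_years) {
    win <- as.Date(c(sprintf("%d-01-01", y), sprintf("%d-12-31", y)))
    pcm <- build_patient_concepts(events, persons, window = win,
                                  dataset_id = sprintf("year-%d", y))
    if (pcm$n_patients == 0L) {
      warning(sprintf("year %d has no clinical events; skipped", y))
      next
    }
    years_used <- c(years_used, y)
    s <- count_singles(pcm)
    s_rand <- poisson_randomize(s, seed = seed,
                                dataset_id = sprintf("year-%d", y),
                                n_p = pcm$n_patients)
    singles_rates[[as.character(y)]] <- data.table::data.table(
      concept_id = s$concept_id,
      true_rate = s$count / pcm$n_patients,
      rand_rate = s_rand$count / pcm$n_patients
    )
    if (include_pairs) {
      p <- count_pairs(pcm)
      p_rand <- poisson_randomize(p, seed = seed,
                                  dataset_id = sprintf("year-%d", y),
                                  n_p = pcm$n_patients)
      pairs_rates[[as.character(y)]] <- data.table::data.table(
        concept_id_1 = p$concept_id_1,
        concept_id_2 = p$concept_id_2,
        true_rate = p$count / pcm$n_patients,
        rand_rate = p_rand$count / pcm$n_patients
      )
    }
  }
  if (length(years_used) == 0L) {
    stop_value("no usable years among full_years")
  }
  n_years <- length(years_used)
  sd_fun <- function(x) {
    ## pad with zero rates for years where the item is absent
    x <- c(x, rep(0, n_years - length(x)))
    if (sd_type == "population") sqrt(mean((x - mean(x))^2)) else sd(x)
  }
  mean_fun <- function(x) sum(x) / n_years

  singles_all <- data.table::rbindlist(singles_rates)
  singles <- singles_all[, .(mean_rate = mean_fun(rand_rate),
                             sd_rate = sd_fun(true_rate)), by = concept_id]
  data.table::setorder(singles, concept_id)

  pairs <- NULL
  if (include_pairs) {
    pairs_all <- data.table::rbindlist(pairs_rates)
    pairs <- pairs_all[, .(mean_rate = mean_fun(rand_rate),
                           sd_rate = sd_fun(true_rate)),
                       by = .(concept_id_1, concept_id_2)]
    data.table::setorder(pairs, concept_id_1, concept_id_2)
  }
  list(singles = singles[], pairs = if (is.null(pairs)) NULL else pairs[],
       years_used = years_used)
}
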