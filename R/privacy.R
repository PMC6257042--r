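## Disclosure-protection pipeline: iatrogenic-code removal, rare-count
## exclusion, Poisson randomization, and a calibration check of the
## randomization's statistical impact.
##
## Pipeline order is fixed: iatrogenic removal -> rare exclusion (true
## count <= threshold) -> Poisson randomization (each released count is one
## draw with lambda equal to the true count). Randomized values of any
## non-negative size are retained, including values <= threshold:
## re-filtering after randomization would bias the released distribution.

#' Privacy pipeline configuration
#'
#' @param min_count exclusion threshold: items with true count
#'   `<= min_count` are removed before randomization (default 10).
#' @param seed master randomization seed.
#' @param alpha significance level used by [randomization_impact()].
#' @return a list of class `privacy_config`.
#' @export
privacy_config <- function(min_count = 10L, seed = 0L, alpha = 0.05) {
  stopifnot(min_count >= 0, alpha > 0, alpha < 1)
  structure(list(min_count = as.integer(min_count),
                 seed = as.integer(seed), alpha = alpha),
            class = "privacy_config")
}

#' Remove iatrogenic concepts from count tables
#'
#' Drops every single count whose concept is in `iatrogenic_ids` and every
#' pair containing such a concept.
#'
#' @param singles single-concept count table ([count_singles()]).
#' @param pairs paired-concept count table ([count_pairs()]), or `NULL`.
#' @param iatrogenic_ids integer concept ids (see [resolve_iatrogenic()]).
#' @return list with filtered `singles` and `pairs`.
#' @export
exclude_iatrogenic <- function(singles, pairs = NULL, iatrogenic_ids = integer()) {
  s <- singles[!concept_id %in% iatrogenic_ids]
  p <- if (is.null(pairs)) NULL else {
    pairs[!(concept_id_1 %in% iatrogenic_ids | concept_id_2 %in% iatrogenic_ids)]
  }
  copy_count_attrs(s, singles)
  if (!is.null(p)) copy_count_attrs(p, pairs)
  list(singles = s, pairs = p)
}

#' Exclude rare counts
#'
#' Removes rows with true count `<= threshold`. Must run on true
#' (pre-randomization) counts.
#'
#' @param counts a single or pair count table with a `count` column.
#' @param threshold exclusion boundary; rows with `count <= threshold` are
#'   dropped (default 10, i.e. counts of 11 and above survive).
#' @return the filtered table.
#' @export
exclude_rare <- function(counts, threshold = 10L) {
  stopifnot(threshold >= 0)
  out <- counts[count > threshold]
  copy_count_attrs(out, counts)
  out[]
}

copy_count_attrs <- function(to, from) {
  data.table::setattr(to, "n_patients", attr(from, "n_patients", exact = TRUE))
  data.table::setattr(to, "dataset_id", attr(from, "dataset_id", exact = TRUE))
  invisible(to)
}

#' Poisson-randomize a count table
#'
#' Replaces every count by a single draw from a Poisson distribution with
#' mean lambda equal to the true count. Each row's draw uses a seed derived
#' from `(seed, dataset_id, concept key)`, so results are deterministic,
#' independent of row order, and independent across datasets. Singles and
#' pairs are randomized independently, which is why released relative
#' frequencies can exceed 1.
#'
#' @param counts single (`concept_id`) or pair (`concept_id_1`,
#'   `concept_id_2`) count table with true counts.
#' @param seed master seed.
#' @param dataset_id dataset label mixed into per-row seeds; defaults to
#'   the table's `dataset_id` attribute.
#' @param n_p patient count used to recompute the `prevalence` column from
#'   the randomized counts; defaults to the table's `n_patients` attribute.
#' @return a table of the same shape with randomized `count` (and
#'   recomputed `prevalence` when available); the true counts are kept in
#'   attribute `"true_count"`, and `"seed"` / `"dataset_id"` record the
#'   randomization linkage.
#' @export
poisson_randomize <- function(counts, seed = 0L, dataset_id = NULL, n_p = NULL) {
  dataset_id <- dataset_id %||% attr(counts, "dataset_id", exact = TRUE) %||% "dataset"
  n_p <- n_p %||% attr(counts, "n_patients", exact = TRUE)
  if (any(counts$count < 0)) stop_value("Poisson rates (true counts) must be non-negative")
  is_pair <- all(c("concept_id_1", "concept_id_2") %in% names(counts))
  key <- if (is_pair) {
    sprintf("pair:%d:%d", counts$concept_id_1, counts$concept_id_2)
  } else {
    sprintf("single:%d", counts$concept_id)
  }
  out <- data.table::copy(counts)
  lambda <- counts$count
  draws <- integer(length(lambda))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  for (i in seq_along(lambda)) {
    set.seed(mix_seed(seed, dataset_id, key[i]))
    draws[i] <- rpois(1L, lambda[i])
  }
  out[, count := draws]
  if ("prevalence" %in% names(out)) {
    if (is.null(n_p)) {
      stop_value("n_p is required to recompute the prevalence column after randomization")
    }
    out[, prevalence := count / n_p]
  }
  copy_count_attrs(out, counts)
  data.table::setattr(out, "true_count", counts$count)
  data.table::setattr(out, "seed", as.integer(seed))
  data.table::setattr(out, "dataset_id", dataset_id)
  out[]
}

#' Fraction of randomized counts significantly different from true counts
#'
#' Per item, a one-degree-of-freedom Pearson goodness-of-fit statistic
#' `(randomized - true)^2 / true` is compared to the chi-square(1) critical
#' value at `alpha`. With lambda large enough for the normal limit of the
#' Poisson to hold, a calibrated randomizer rejects in about `alpha` of
#' items.
#'
#' @param true_counts,randomized_counts numeric vectors, or count tables
#'   sharing the same concept key columns (they are aligned by key).
#' @param alpha significance level.
#' @return a list with `n_significant`, `n_total`, `fraction`.
#' @export
randomization_impact <- function(true_counts, randomized_counts, alpha = 0.05) {
  if (is.data.frame(true_counts)) {
    keys <- intersect(c("concept_id", "concept_id_1", "concept_id_2"),
                      names(true_counts))
    if (!all(keys %in% names(randomized_counts))) {
      stop_value("true and randomized tables have different key columns")
    }
    m <- merge(data.table::as.data.table(true_counts)[, c(keys, "count"), with = FALSE],
               data.table::as.data.table(randomized_counts)[, c(keys, "count"), with = FALSE],
               by = keys, suffixes = c("_true", "_rand"))
    if (nrow(m) != nrow(true_counts) || nrow(m) != nrow(randomized_counts)) {
      stop_value("true and randomized tables do not align one-to-one")
    }
    t_vec <- m$count_true
    r_vec <- m$count_rand
  } else {
    if (length(true_counts) != length(randomized_counts)) {
      stop_value("true and randomized vectors differ in length")
    }
    t_vec <- true_counts
    r_vec <- randomized_counts
  }
  if (any(t_vec <= 0)) stop_value("true counts must be positive")
  stat <- (r_vec - t_vec)^2 / t_vec
  crit <- qchisq(1 - alpha, df = 1)
  n_sig <- sum(stat > crit)
  list(n_significant = n_sig, n_total = length(stat),
       fraction = n_sig / length(stat))
}

#' Calibration simulation for the randomization impact
#'
#' Simulates true counts spanning the released count range (log-uniform
#' between `lambda_range[1]` and `lambda_range[2]`, rounded to integers),
#' Poisson-randomizes them once through [poisson_randomize()], and reports
#' the fraction flagged by [randomization_impact()] at `alpha`. For a
#' calibrated randomizer the fraction approaches `alpha`.
#'
#' @param n number of simulated counts.
#' @param lambda_range range of true counts.
#' @param alpha significance level.
#' @param seed simulation and randomization seed.
#' @return the list returned by [randomization_impact()], plus `alpha`
#'   and `n`.
#' @export
calibrate_randomization_impact <- function(n = 50000L,
                                           lambda_range = c(50, 1e5),
                                           alpha = 0.05, seed = 0L) {
  stopifnot(n >= 1, lambda_range[1] > 0, lambda_range[1] <= lambda_range[2])
  set.seed(mix_seed(seed, "impact-calibration"))
  true <- round(exp(runif(n, log(lambda_range[1]), log(lambda_range[2]))))
  tab <- data.table::data.table(concept_id = seq_len(n), count = as.integer(true))
  rand <- poisson_randomize(tab, seed = seed, dataset_id = "impact-calibration")
  res <- randomization_impact(tab$count, rand$count, alpha = alpha)
  c(res, list(alpha = alpha, n = n))
}
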