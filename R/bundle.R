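## Released flat-file bundles.
##
## A bundle holds, per dataset (e.g. "lifetime" and "5year"), the released
## single-concept counts, paired-concept counts, and the single / paired
## annual-deviation tables, plus one shared concept-definition table. On
## disk this is a set of tab-delimited text files:
##   <dataset_id>_single_concepts.txt            concept_id, count, prevalence
##   <dataset_id>_paired_concepts.txt            concept_id_1, concept_id_2, count, prevalence
##   <dataset_id>_single_concept_deviations.txt  concept_id, mean_prevalence, sd_prevalence
##   <dataset_id>_paired_concept_deviations.txt  concept_id_1, concept_id_2, mean_cooccurrence, sd_cooccurrence
##   concepts.txt                                the six concept columns
##   dataset_metadata.txt                        dataset_id, patient_count, window_start, window_end
## All frequencies are relative to a maximum of 1.0 (1.0 = 100%).

.singles_cols <- c("concept_id", "count", "prevalence")
.pairs_cols <- c("concept_id_1", "concept_id_2", "count", "prevalence")
.singles_dev_cols <- c("concept_id", "mean_prevalence", "sd_prevalence")
.pairs_dev_cols <- c("concept_id_1", "concept_id_2", "mean_cooccurrence",
                     "sd_cooccurrence")

#' Assemble a released-data bundle
#'
#' @param datasets named list; each element is a list with components
#'   `singles`, `pairs` (released count tables), optionally `singles_dev`,
#'   `pairs_dev` (from [annual_deviations()], renamed to the file schema),
#'   `patient_count` (N_P), and `window` (`Date` pair or `NULL`).
#' @param concepts concept dictionary covering every referenced concept id.
#' @return an object of class `cohd_bundle`.
#' @export
cohd_bundle <- function(datasets, concepts) {
  stopifnot(is.list(datasets), length(names(datasets)) == length(datasets))
  for (id in names(datasets)) {
    d <- datasets[[id]]
    check_columns(d$singles, .singles_cols, paste0(id, "$singles"))
    check_columns(d$pairs, .pairs_cols, paste0(id, "$pairs"))
    if (any(d$pairs$concept_id_1 >= d$pairs$concept_id_2)) {
      stop_integrity("pairs of dataset '%s' are not in canonical order", id)
    }
    if (is.null(d$patient_count)) {
      datasets[[id]]$patient_count <- attr(d$singles, "n_patients", exact = TRUE)
    }
  }
  structure(list(datasets = datasets, concepts = concepts),
            class = "cohd_bundle")
}

#' @export
print.cohd_bundle <- function(x, ...) {
  cat(sprintf("<cohd_bundle> %d dataset(s): %s; %d concepts\n",
              length(x$datasets), paste(names(x$datasets), collapse = ", "),
              nrow(x$concepts)))
  invisible(x)
}

write_freq_table <- function(dt, path, freq_cols, digits, sep) {
  out <- data.table::copy(dt)
  for (cl in intersect(freq_cols, names(out))) {
    data.table::set(out, j = cl, value = render_freq(out[[cl]], digits))
  }
  data.table::fwrite(out, path, sep = sep, quote = FALSE)
}

#' Write a bundle to a directory of tab-delimited files
#'
#' Rows are written in canonical order (singles by `concept_id`, pairs by
#' the id pair), frequencies rendered with `digits` significant digits
#' (`NA` = full precision), so the output is deterministic and
#' `write -> read -> write` round trips are byte-identical.
#'
#' @param bundle a [cohd_bundle()].
#' @param dir output directory (created if needed).
#' @param digits significant digits for frequency columns (default 6).
#' @param sep field separator.
#' @return invisibly, the vector of files written.
#' @export
write_bundle <- function(bundle, dir, digits = 6L, sep = "\t") {
  stopifnot(inherits(bundle, "cohd_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  meta <- data.table::data.table(dataset_id = character(),
                                 patient_count = integer(),
                                 window_start = character(),
                                 window_end = character())
  for (id in names(bundle$datasets)) {
    d <- bundle$datasets[[id]]
    s <- data.table::copy(d$singles)[, .singles_cols, with = FALSE]
    data.table::setorder(s, concept_id)
    p <- data.table::copy(d$pairs)[, .pairs_cols, with = FALSE]
    data.table::setorder(p, concept_id_1, concept_id_2)
    f1 <- file.path(dir, sprintf("%s_single_concepts.txt", id))
    f2 <- file.path(dir, sprintf("%s_paired_concepts.txt", id))
    write_freq_table(s, f1, "prevalence", digits, sep)
    write_freq_table(p, f2, "prevalence", digits, sep)
    written <- c(written, f1, f2)
    if (!is.null(d$singles_dev)) {
      sd_ <- data.table::copy(d$singles_dev)[, .singles_dev_cols, with = FALSE]
      data.table::setorder(sd_, concept_id)
      f3 <- file.path(dir, sprintf("%s_single_concept_deviations.txt", id))
      write_freq_table(sd_, f3, c("mean_prevalence", "sd_prevalence"), digits, sep)
      written <- c(written, f3)
    }
    if (!is.null(d$pairs_dev)) {
      pd <- data.table::copy(d$pairs_dev)[, .pairs_dev_cols, with = FALSE]
      data.table::setorder(pd, concept_id_1, concept_id_2)
      f4 <- file.path(dir, sprintf("%s_paired_concept_deviations.txt", id))
      write_freq_table(pd, f4, c("mean_cooccurrence", "sd_cooccurrence"),
                       digits, sep)
      written <- c(written, f4)
    }
    meta <- rbind(meta, data.table::data.table(
      dataset_id = id,
      patient_count = as.integer(d$patient_count %||% NA_integer_),
      window_start = if (is.null(d$window)) "" else as.character(d$window[1]),
      window_end = if (is.null(d$window)) "" else as.character(d$window[2])
    ))
  }
  fc <- file.path(dir, "concepts.txt")
  cdt <- data.table::copy(bundle$concepts)[, .concept_columns, with = FALSE]
  data.table::setorder(cdt, concept_id)
  data.table::fwrite(cdt, fc, sep = sep, quote = FALSE)
  fm <- file.path(dir, "dataset_metadata.txt")
  data.table::fwrite(meta, fm, sep = sep, quote = FALSE)
  invisible(c(written, fc, fm))
}

read_checked <- function(path, required, sep) {
  dt <- data.table::fread(path, sep = sep, header = TRUE, data.table = TRUE,
                          integer64 = "double",
                          colClasses = if (basename(path) == "concepts.txt")
                            list(character = 2:6) else NULL)
  check_columns(dt, required, path)
  dt[, required, with = FALSE]
}

#' Read a bundle from a directory
#'
#' Datasets are discovered from `*_single_concepts.txt` file names. Pair
#' rows violating the canonical id order are normalized with a warning.
#' Missing deviation files leave the corresponding component `NULL`;
#' a missing `dataset_metadata.txt` leaves patient counts `NA` (association
#' queries are then unavailable).
#'
#' @param dir directory written by [write_bundle()].
#' @param sep field separator.
#' @return a [cohd_bundle()].
#' @export
read_bundle <- function(dir, sep = "\t") {
  single_files <- list.files(dir, pattern = "_single_concepts\\.txt$")
  if (length(single_files) == 0L) {
    stop_schema("no '*_single_concepts.txt' files found in '%s'", dir)
  }
  ids <- sub("_single_concepts\\.txt$", "", single_files)
  meta <- NULL
  fm <- file.path(dir, "dataset_metadata.txt")
  if (file.exists(fm)) {
    meta <- read_checked(fm, c("dataset_id", "patient_count",
                               "window_start", "window_end"), sep)
  }
  datasets <- list()
  for (id in ids) {
    s <- read_checked(file.path(dir, sprintf("%s_single_concepts.txt", id)),
                      .singles_cols, sep)
    p <- read_checked(file.path(dir, sprintf("%s_paired_concepts.txt", id)),
                      .pairs_cols, sep)
    flipped <- p$concept_id_1 > p$concept_id_2
    if (any(flipped)) {
      warning(sprintf("%d pair row(s) of dataset '%s' were not in canonical order; normalized",
                      sum(flipped), id))
      tmp <- p$concept_id_1[flipped]
      p[flipped, concept_id_1 := concept_id_2]
      p[flipped, concept_id_2 := tmp]
      data.table::setorder(p, concept_id_1, concept_id_2)
    }
    f3 <- file.path(dir, sprintf("%s_single_concept_deviations.txt", id))
    f4 <- file.path(dir, sprintf("%s_paired_concept_deviations.txt", id))
    sdv <- if (file.exists(f3)) read_checked(f3, .singles_dev_cols, sep) else NULL
    pdv <- if (file.exists(f4)) read_checked(f4, .pairs_dev_cols, sep) else NULL
    n_p <- NA_integer_
    window <- NULL
    if (!is.null(meta) && id %in% meta$dataset_id) {
      row <- meta[meta$dataset_id == id][1L]
      n_p <- row$patient_count
      if (nzchar(row$window_start %||% "") && !is.na(row$window_start)) {
        window <- as.Date(c(row$window_start, row$window_end))
      }
    }
    data.table::setattr(s, "n_patients", n_p)
    data.table::setattr(p, "n_patients", n_p)
    data.table::setattr(s, "dataset_id", id)
    data.table::setattr(p, "dataset_id", id)
    datasets[[id]] <- list(singles = s, pairs = p, singles_dev = sdv,
                           pairs_dev = pdv, patient_count = n_p,
                           window = window)
  }
  concepts <- read_checked(file.path(dir, "concepts.txt"), .concept_columns, sep)
  data.table::setkey(concepts, concept_id)
  cohd_bundle(datasets, concepts)
}

#' Run the full release pipeline for one dataset window
#'
#' Builds patient concept sets, counts singles and pairs, then applies the
#' disclosure-protection pipeline in its fixed order: iatrogenic-code
#' removal, rare-count exclusion (true count <= threshold), Poisson
#' randomization. Optionally computes annual deviation tables over
#' `full_years` (randomized means, true-count standard deviations).
#'
#' @param events,persons,window,dataset_id as in [build_patient_concepts()].
#' @param config a [privacy_config()].
#' @param iatrogenic_ids integer concept ids to purge.
#' @param full_years optional years for [annual_deviations()].
#' @return a dataset list suitable for [cohd_bundle()]: released `singles`,
#'   `pairs`, optional `singles_dev` / `pairs_dev`, `patient_count`,
#'   `window`, plus `true_singles` / `true_pairs` for internal validation.
#' @export
compute_dataset <- function(events, persons, window = NULL,
                            dataset_id = "dataset",
                            config = privacy_config(),
                            iatrogenic_ids = integer(),
                            full_years = NULL) {
  pcm <- build_patient_concepts(events, persons, window = window,
                                dataset_id = dataset_id)
  singles <- count_singles(pcm)
  pairs <- count_pairs(pcm)
  filt <- exclude_iatrogenic(singles, pairs, iatrogenic_ids)
  singles_kept <- exclude_rare(filt$singles, config$min_count)
  pairs_kept <- exclude_rare(filt$pairs, config$min_count)
  released_singles <- poisson_randomize(singles_kept, seed = config$seed,
                                        dataset_id = dataset_id,
                                        n_p = pcm$n_patients)
  released_pairs <- poisson_randomize(pairs_kept, seed = config$seed,
                                      dataset_id = dataset_id,
                                      n_p = pcm$n_patients)
  out <- list(singles = released_singles, pairs = released_pairs,
              singles_dev = NULL, pairs_dev = NULL,
              patient_count = pcm$n_patients, window = window,
              true_singles = singles_kept, true_pairs = pairs_kept)
  if (!is.null(full_years)) {
    dev <- annual_deviations(events, persons, full_years, seed = config$seed)
    sdv <- dev$singles[, .(concept_id, mean_prevalence = mean_rate,
                           sd_prevalence = sd_rate)]
    pdv <- dev$pairs[, .(concept_id_1, concept_id_2,
                         mean_cooccurrence = mean_rate,
                         sd_cooccurrence = sd_rate)]
    ## deviations are released only for items surviving the exclusion
    out$singles_dev <- sdv[concept_id %in% released_singles$concept_id]
    out$pairs_dev <- merge(pdv,
                           released_pairs[, .(concept_id_1, concept_id_2)],
                           by = c("concept_id_1", "concept_id_2"))
  }
  out
}
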