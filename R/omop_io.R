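## Readers for OMOP CDM v5-style delimited extracts.
##
## All readers accept tab-delimited files with a header row by default
## (the flat-file convention used throughout the package); `sep = ","`
## switches to CSV.

.concept_columns <- c("concept_id", "concept_name", "domain_id",
                      "vocabulary_id", "concept_class_id", "concept_code")

.event_defaults <- list(
  condition = list(id_col = "condition_concept_id",
                   date_col = "condition_start_date"),
  drug      = list(id_col = "drug_concept_id",
                   date_col = "drug_exposure_start_date"),
  procedure = list(id_col = "procedure_concept_id",
                   date_col = "procedure_date")
)

#' Read an OMOP concept table into a concept dictionary
#'
#' Reads a delimited `concept` extract with the six standard columns
#' (`concept_id`, `concept_name`, `domain_id`, `vocabulary_id`,
#' `concept_class_id`, `concept_code`) into a [data.table::data.table]
#' keyed by `concept_id`.
#'
#' Concept names are limited to 255 characters in the OMOP CDM. Longer
#' names are an error unless `truncate_names = TRUE`, in which case they
#' are truncated to 255 characters.
#'
#' @param path path to the delimited file.
#' @param sep field separator (default tab).
#' @param truncate_names truncate over-long concept names instead of
#'   raising a schema error.
#' @return a `data.table` keyed by `concept_id`, one row per concept.
#' @export
read_concepts <- function(path, sep = "\t", truncate_names = FALSE) {
  if (!file.exists(path)) stop_value("concept file not found: %s", path)
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          colClasses = "character", data.table = TRUE)
  check_columns(dt, .concept_columns, path)
  dt <- dt[, .concept_columns, with = FALSE]
  dt[, concept_id := as_count_integer(concept_id, "concept_id")]
  if (anyDuplicated(dt$concept_id)) {
    dup <- dt$concept_id[duplicated(dt$concept_id)][1L]
    stop_integrity("duplicate concept_id %d in '%s'", dup, path)
  }
  too_long <- nchar(dt$concept_name) > 255L
  if (any(too_long)) {
    if (truncate_names) {
      dt[too_long, concept_name := substr(concept_name, 1L, 255L)]
    } else {
      stop_schema("%d concept name(s) exceed the 255 character OMOP limit in '%s'",
                  sum(too_long), path)
    }
  }
  data.table::setkey(dt, concept_id)
  dt[]
}

#' Read clinical events from an OMOP event table extract
#'
#' Reads one of the three OMOP event tables (`condition_occurrence`,
#' `drug_exposure`, `procedure_occurrence`) into a normalized event table
#' with columns `person_id`, `concept_id`, `event_date`, `source_table`.
#'
#' Rows whose concept id is 0 (OMOP's "no matching concept" sentinel) are
#' dropped and tallied; they never enter any count. Unparseable dates are
#' either a row-level error (`on_bad_date = "fail"`, the default) or
#' dropped and tallied (`"skip"`). The drop tallies are attached as the
#' `"dropped"` attribute: a list with `zero_concept`, `bad_date`, and
#' `rows_read`.
#'
#' @param path path to the delimited file.
#' @param source_table one of `"condition"`, `"drug"`, `"procedure"`;
#'   selects the default concept-id and date columns.
#' @param sep field separator.
#' @param id_col,date_col override the default OMOP column names.
#' @param on_bad_date `"fail"` or `"skip"`.
#' @return a `data.table` of clinical events.
#' @export
read_events <- function(path,
                        source_table = c("condition", "drug", "procedure"),
                        sep = "\t", id_col = NULL, date_col = NULL,
                        on_bad_date = c("fail", "skip")) {
  source_table <- match.arg(source_table)
  on_bad_date <- match.arg(on_bad_date)
  if (!file.exists(path)) stop_value("event file not found: %s", path)
  defaults <- .event_defaults[[source_table]]
  id_col <- id_col %||% defaults$id_col
  date_col <- date_col %||% defaults$date_col

  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          colClasses = "character", data.table = TRUE)
  check_columns(dt, c("person_id", id_col, date_col), path)
  rows_read <- nrow(dt)

  out <- data.table::data.table(
    person_id = as_count_integer(dt[["person_id"]], "person_id"),
    concept_id = as_count_integer(dt[[id_col]], id_col),
    event_date = parse_omop_date(dt[[date_col]])
  )

  bad <- which(is.na(out$event_date))
  if (length(bad) > 0L && on_bad_date == "fail") {
    stop_value("unparseable %s value(s) at data row(s) %s of '%s'",
               date_col, paste(head(bad, 5L), collapse = ", "), path)
  }
  n_bad <- length(bad)
  if (n_bad > 0L) out <- out[-bad]
  zero <- out$concept_id == 0L
  n_zero <- sum(zero)
  if (n_zero > 0L) out <- out[!zero]
  out[, source_table := source_table]
  data.table::setattr(out, "dropped",
                      list(zero_concept = n_zero, bad_date = n_bad,
                           rows_read = rows_read))
  out[]
}

## Date-part of an OMOP date or datetime string; NA for unparseable values
## (including impossible calendar dates like 2014-02-30).
parse_omop_date <- function(x) {
  x <- substr(trimws(x), 1L, 10L)
  as.Date(x, format = "%Y-%m-%d", optional = TRUE)
}

#' Read the OMOP person table
#'
#' Extracts `person_id` and the three demographic concept-id columns
#' (`gender_concept_id`, `race_concept_id`, `ethnicity_concept_id`).
#' A demographic concept id of 0 means unmapped and is ignored downstream.
#'
#' @inheritParams read_concepts
#' @return a `data.table`, one row per person, keyed by `person_id`.
#' @export
read_persons <- function(path, sep = "\t") {
  if (!file.exists(path)) stop_value("person file not found: %s", path)
  cols <- c("person_id", "gender_concept_id", "race_concept_id",
            "ethnicity_concept_id")
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          integer64 = "double", data.table = TRUE)
  check_columns(dt, cols, path)
  dt <- dt[, cols, with = FALSE]
  for (cl in cols) data.table::set(dt, j = cl, value = as_count_integer(dt[[cl]], cl))
  if (anyDuplicated(dt$person_id)) {
    dup <- dt$person_id[duplicated(dt$person_id)][1L]
    stop_integrity("duplicate person_id %d in '%s'; person ids must uniquely identify patients",
                   dup, path)
  }
  data.table::setkey(dt, person_id)
  dt[]
}

#' Load a list of iatrogenic concept codes
#'
#' Reads a two-column delimited file of `(vocabulary_id, concept_code)`
#' pairs naming concept codes that describe complications of medical care
#' (e.g. ICD-9-CM 996.82, complication of transplanted liver). These are
#' purged from released tables by [exclude_iatrogenic()].
#'
#' @inheritParams read_concepts
#' @return a `data.table` with columns `vocabulary_id`, `concept_code`
#'   (unique pairs).
#' @export
load_iatrogenic_codes <- function(path, sep = "\t") {
  if (!file.exists(path)) stop_value("iatrogenic code file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) == 0L) {
    return(data.table::data.table(vocabulary_id = character(),
                                  concept_code = character()))
  }
  fields <- strsplit(lines, sep, fixed = TRUE)
  n_fields <- lengths(fields)
  bad <- which(n_fields != 2L)
  if (length(bad) > 0L) {
    stop_schema("malformed iatrogenic code row at line %d of '%s' (expected 2 fields, got %d)",
                bad[1L], path, n_fields[bad[1L]])
  }
  header <- fields[[1L]]
  start <- if (identical(tolower(header), c("vocabulary_id", "concept_code"))) 2L else 1L
  if (start > length(fields)) {
    return(data.table::data.table(vocabulary_id = character(),
                                  concept_code = character()))
  }
  body <- fields[seq(start, length(fields))]
  out <- data.table::data.table(
    vocabulary_id = trimws(vapply(body, `[`, character(1), 1L)),
    concept_code = trimws(vapply(body, `[`, character(1), 2L))
  )
  unique(out)
}

#' Resolve iatrogenic codes to concept ids through a concept dictionary
#'
#' @param codes table from [load_iatrogenic_codes()].
#' @param concepts concept dictionary from [read_concepts()].
#' @param quiet suppress the message about unmatched codes.
#' @return integer vector of matching concept ids (possibly empty).
#' @export
resolve_iatrogenic <- function(codes, concepts, quiet = FALSE) {
  if (nrow(codes) == 0L) return(integer())
  hit <- merge(codes, concepts[, .(concept_id, vocabulary_id, concept_code)],
               by = c("vocabulary_id", "concept_code"))
  n_miss <- nrow(codes) - nrow(unique(hit[, .(vocabulary_id, concept_code)]))
  if (n_miss > 0L && !quiet) {
    message(sprintf("%d iatrogenic code(s) matched no concept in the dictionary", n_miss))
  }
  sort(unique(hit$concept_id))
}

#' Write an OMOP-shaped cohort to delimited files
#'
#' Writes the five tables of a cohort (as returned by [generate_cohort()])
#' as delimited text files named `person`, `condition_occurrence`,
#' `drug_exposure`, `procedure_occurrence`, `concept` with extension
#' `.tsv` (or `.csv`). The output is readable by [read_persons()],
#' [read_events()], and [read_concepts()].
#'
#' @param cohort a list of tables as returned by [generate_cohort()].
#' @param dir output directory (created if needed).
#' @param sep field separator.
#' @return invisibly, the vector of file paths written.
#' @export
write_cohort <- function(cohort, dir, sep = "\t") {
  stopifnot(is.list(cohort))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (sep == ",") ".csv" else ".tsv"
  tables <- c("person", "condition_occurrence", "drug_exposure",
              "procedure_occurrence", "concept")
  paths <- character(0)
  for (tb in tables) {
    if (is.null(cohort[[tb]])) next
    p <- file.path(dir, paste0(tb, ext))
    data.table::fwrite(cohort[[tb]], p, sep = sep, quote = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
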