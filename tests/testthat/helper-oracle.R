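# Brute-force oracles, independent of the data.table code paths they check.

# Per-patient concept sets as a plain named list of integer vectors,
# computed with base R only.
oracle_patient_sets <- function(events, persons, window = NULL) {
  ev <- as.data.frame(events)
  if (!is.null(window)) {
    ev <- ev[ev$event_date >= window[1] & ev$event_date <= window[2], , drop = FALSE]
  }
  ev <- ev[ev$concept_id != 0L, , drop = FALSE]
  sets <- list()
  for (i in seq_len(nrow(ev))) {
    pid <- as.character(ev$person_id[i])
    sets[[pid]] <- union(sets[[pid]], ev$concept_id[i])
  }
  per <- as.data.frame(persons)
  for (pid in names(sets)) {
    row <- per[per$person_id == as.integer(pid), , drop = FALSE]
    if (nrow(row) == 1L) {
      for (cid in c(row$gender_concept_id, row$race_concept_id,
                    row$ethnicity_concept_id)) {
        if (cid != 0L) sets[[pid]] <- union(sets[[pid]], cid)
      }
    }
  }
  sets
}

# Single counts by explicit double loop.
oracle_single_counts <- function(sets) {
  all_ids <- sort(unique(unlist(sets)))
  counts <- integer(length(all_ids))
  for (j in seq_along(all_ids)) {
    for (s in sets) if (all_ids[j] %in% s) counts[j] <- counts[j] + 1L
  }
  data.frame(concept_id = all_ids, count = counts)
}

# Pair counts by explicit enumeration of every unordered pair per patient.
oracle_pair_counts <- function(sets) {
  tally <- new.env(parent = emptyenv())
  for (s in sets) {
    s <- sort(s)
    if (length(s) < 2L) next
    for (i in seq_len(length(s) - 1L)) {
      for (j in seq((i + 1L), length(s))) {
        key <- paste(s[i], s[j])
        tally[[key]] <- (if (is.null(tally[[key]])) 0L else tally[[key]]) + 1L
      }
    }
  }
  keys <- ls(tally)
  if (length(keys) == 0L) {
    return(data.frame(concept_id_1 = integer(), concept_id_2 = integer(),
                      count = integer()))
  }
  parts <- do.call(rbind, strsplit(keys, " ", fixed = TRUE))
  out <- data.frame(concept_id_1 = as.integer(parts[, 1]),
                    concept_id_2 = as.integer(parts[, 2]),
                    count = vapply(keys, function(k) tally[[k]], integer(1)))
  out <- out[order(out$concept_id_1, out$concept_id_2), ]
  rownames(out) <- NULL
  out
}

# A small catalog in which nearly every patient has at least one clinical
# event, so the included-patient population is close to the generated one.
dense_catalog <- function() {
  data.frame(
    concept_id = c(11L, 12L, 13L, 14L, 15L, 16L),
    domain = c("Condition", "Condition", "Drug", "Drug", "Procedure", "Condition"),
    prevalence = c(0.30, 0.15, 0.20, 0.10, 0.12, 0.95)
  )
}

write_tsv_lines <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
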