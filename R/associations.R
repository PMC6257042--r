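## Concept association measures over released counts.
##
## Three complementary views of the dependence between two concepts:
##   chi-square  — Pearson statistic on the 2x2 patient contingency table;
##   relative frequency — FR(C1|C2) = N12 / N2, an empirical analogue of
##                 the conditional probability of C1 given C2;
##   log ratio   — LR = ln(N12 * N_P / (N1 * N2)), the natural log of the
##                 observed pair count over the count expected under
##                 independence; sign gives direction, magnitude strength.

#' Relative frequency FR(C1 | C2)
#'
#' @param n12 pair patient count.
#' @param n2 base concept patient count (> 0).
#' @return `n12 / n2` (vectorized). True counts give values `<= 1`;
#'   independently randomized counts may exceed 1.
#' @export
relative_frequency <- function(n12, n2) {
  if (any(n2 <= 0)) stop_value("base concept count must be positive")
  if (any(n12 < 0)) stop_value("pair counts must be non-negative")
  n12 / n2
}

#' Expected pair count under independence
#'
#' @param n1,n2 single concept patient counts.
#' @param n_p dataset patient count.
#' @return `n1 * n2 / n_p` (vectorized).
#' @export
expected_count <- function(n1, n2, n_p) {
  if (any(n_p <= 0)) stop_value("N_P must be positive")
  n1 * n2 / n_p
}

#' Observed-expected log frequency ratio
#'
#' @param n12 observed pair count (> 0; a zero observed count has no
#'   finite log ratio and is signalled as an error).
#' @param n1,n2 single concept counts (> 0).
#' @param n_p dataset patient count (> 0).
#' @return natural log of `n12 * n_p / (n1 * n2)` (vectorized).
#' @export
log_ratio <- function(n12, n1, n2, n_p) {
  if (any(n1 <= 0) || any(n2 <= 0) || any(n_p <= 0)) {
    stop_value("single counts and N_P must be positive")
  }
  if (any(n12 <= 0)) {
    stop_value("log ratio is undefined for a zero pair count")
  }
  log(n12 * n_p / (n1 * n2))
}

#' Pearson chi-square test of a concept pair's 2x2 contingency table
#'
#' Builds the patient-level 2x2 table
#' `[n12, n1 - n12; n2 - n12, n_p - n1 - n2 + n12]` and computes the
#' Pearson statistic with 1 degree of freedom, without continuity
#' correction. True counts always yield non-negative cells; independently
#' randomized counts can violate this, which raises an error naming the
#' offending cell.
#'
#' @inheritParams log_ratio
#' @param n12 pair count (>= 0).
#' @return a list with vectors `chi2` and `p_value`.
#' @export
chi_square_pair <- function(n12, n1, n2, n_p) {
  a <- n12
  b <- n1 - n12
  c_ <- n2 - n12
  d <- n_p - n1 - n2 + n12
  cells <- rbind(a, b, c_, d)
  labels <- c("both", "concept 1 only", "concept 2 only", "neither")
  bad <- which(cells < 0, arr.ind = TRUE)
  if (length(bad) > 0L) {
    stop_value("inconsistent counts: cell '%s' is negative", labels[bad[1L, 1L]])
  }
  e_a <- n1 * n2 / n_p
  e_b <- n1 * (n_p - n2) / n_p
  e_c <- (n_p - n1) * n2 / n_p
  e_d <- (n_p - n1) * (n_p - n2) / n_p
  chi2 <- (a - e_a)^2 / e_a + (b - e_b)^2 / e_b +
    (c_ - e_c)^2 / e_c + (d - e_d)^2 / e_d
  list(chi2 = unname(chi2),
       p_value = unname(pchisq(chi2, df = 1, lower.tail = FALSE)))
}

#' All association measures for one concept pair
#'
#' @inheritParams chi_square_pair
#' @return a one-row `data.table` with `chi2`, `p_value`,
#'   `relative_frequency` (FR(C1|C2)), `log_ratio`, `expected_count`.
#' @export
concept_association <- function(n12, n1, n2, n_p) {
  cs <- chi_square_pair(n12, n1, n2, n_p)
  data.table::data.table(
    chi2 = cs$chi2,
    p_value = cs$p_value,
    relative_frequency = relative_frequency(n12, n2),
    log_ratio = log_ratio(n12, n1, n2, n_p),
    expected_count = expected_count(n1, n2, n_p)
  )
}

#' Most frequent concepts, optionally by domain
#'
#' Ranks single-concept counts descending, ties broken by ascending
#' concept id.
#'
#' @param singles single-concept count table.
#' @param concepts concept dictionary (required when `domain` is given;
#'   when supplied, names and domains are joined onto the result).
#' @param domain optional domain label filter (e.g. `"Condition"`).
#' @param k number of rows to return (>= 0).
#' @return a `data.table` of at most `k` rows.
#' @export
most_frequent <- function(singles, concepts = NULL, domain = NULL, k = 10L) {
  stopifnot(k >= 0)
  out <- data.table::copy(singles)
  if (!is.null(concepts)) {
    out <- merge(out, concepts[, .(concept_id, concept_name, domain_id)],
                 by = "concept_id", all.x = TRUE, sort = FALSE)
  }
  if (!is.null(domain)) {
    if (is.null(concepts)) stop_value("a concept dictionary is required to filter by domain")
    valid <- sort(unique(concepts$domain_id))
    if (!domain %in% valid) {
      stop_value("unknown domain '%s'; valid domains: %s",
                 domain, paste(valid, collapse = ", "))
    }
    out <- out[domain_id == domain]
  }
  data.table::setorder(out, -count, concept_id)
  head(out, k)
}

#' Concepts most associated with an anchor concept
#'
#' Returns, for all released pairs containing `anchor_id`, the partner
#' concept together with the pair count and the three association measures,
#' ranked by the chosen metric (descending, ties by ascending partner id).
#' For `metric = "relative_frequency"` the conditioning is
#' FR(anchor | partner) = pair count / partner count: among patients with
#' the partner concept, the fraction also observed with the anchor.
#'
#' @param anchor_id concept id that must be present in `singles`.
#' @param singles,pairs released count tables.
#' @param n_p dataset patient count; defaults to the `n_patients` attribute
#'   of `singles`.
#' @param metric one of `"count"`, `"relative_frequency"`, `"log_ratio"`.
#' @param concepts optional concept dictionary for names / domain filter.
#' @param domain optional partner domain filter.
#' @param k number of rows.
#' @return a `data.table` of at most `k` rows with columns `concept_id`
#'   (partner), `pair_count`, `base_count` (partner count),
#'   `anchor_count`, `relative_frequency`, `log_ratio`, `chi2`, `p_value`,
#'   `expected_count`, plus name/domain when `concepts` is given.
#' @export
top_associated <- function(anchor_id, singles, pairs, n_p = NULL,
                           metric = c("count", "relative_frequency", "log_ratio"),
                           concepts = NULL, domain = NULL, k = 10L) {
  metric <- match.arg(metric)
  n_p <- n_p %||% attr(singles, "n_patients", exact = TRUE)
  if (is.null(n_p)) stop_value("n_p is required (or supply a singles table carrying it)")
  if (!anchor_id %in% singles$concept_id) {
    stop_value("anchor concept %d not found in the released single counts", anchor_id)
  }
  n1 <- singles[concept_id == anchor_id, count]

  hit <- pairs[concept_id_1 == anchor_id | concept_id_2 == anchor_id]
  if (nrow(hit) == 0L) return(empty_association_table())
  hit[, partner_id := ifelse(concept_id_1 == anchor_id, concept_id_2, concept_id_1)]
  res <- merge(hit[, .(concept_id = partner_id, pair_count = count)],
               singles[, .(concept_id, base_count = count)],
               by = "concept_id")
  if (nrow(res) == 0L) return(empty_association_table())
  res[, anchor_count := n1]
  res[, relative_frequency := relative_frequency(pair_count, base_count)]
  res[, log_ratio := log_ratio(pair_count, anchor_count, base_count, n_p)]
  cs <- tryCatch(chi_square_pair(res$pair_count, res$anchor_count,
                                 res$base_count, n_p),
                 omopfreq_value_error = function(e) NULL)
  if (!is.null(cs)) {
    res[, `:=`(chi2 = cs$chi2, p_value = cs$p_value)]
  } else {
    ## randomized counts can make some 2x2 cells negative; compute row-wise
    rows <- lapply(seq_len(nrow(res)), function(i) {
      tryCatch(chi_square_pair(res$pair_count[i], res$anchor_count[i],
                               res$base_count[i], n_p),
               omopfreq_value_error = function(e) list(chi2 = NA_real_,
                                                       p_value = NA_real_))
    })
    res[, `:=`(chi2 = vapply(rows, `[[`, numeric(1), "chi2"),
               p_value = vapply(rows, `[[`, numeric(1), "p_value"))]
  }
  res[, expected_count := expected_count(anchor_count, base_count, n_p)]
  if (!is.null(concepts)) {
    res <- merge(res, concepts[, .(concept_id, concept_name, domain_id)],
                 by = "concept_id", all.x = TRUE, sort = FALSE)
    if (!is.null(domain)) {
      valid <- sort(unique(concepts$domain_id))
      if (!domain %in% valid) {
        stop_value("unknown domain '%s'; valid domains: %s",
                   domain, paste(valid, collapse = ", "))
      }
      res <- res[domain_id == domain]
    }
  } else if (!is.null(domain)) {
    stop_value("a concept dictionary is required to filter by domain")
  }
  res[, metric_value := switch(metric,
                               count = as.numeric(pair_count),
                               relative_frequency = relative_frequency,
                               log_ratio = log_ratio)]
  data.table::setorder(res, -metric_value, concept_id)
  res[, metric_value := NULL]
  head(res, k)
}

empty_association_table <- function() {
  data.table::data.table(concept_id = integer(), pair_count = integer(),
                         base_count = integer(), anchor_count = integer(),
                         relative_frequency = numeric(), log_ratio = numeric(),
                         chi2 = numeric(), p_value = numeric(),
                         expected_count = numeric())
}
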