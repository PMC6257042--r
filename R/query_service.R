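## In-process JSON query interface over a released bundle.
##
## Endpoints mirror the four resource groups of the public service surface
## (/metadata, /omop, /frequencies, /association). Each endpoint is a thin
## view over the library functions: the service adds no computation of its
## own and is read-only and stateless between requests. Responses are
## plain R lists serializable with jsonlite; errors are structured records
## with a `status` field rather than R conditions, so a transport layer
## can pass them through unchanged.

#' Create a query API over a bundle
#'
#' @param bundle a [cohd_bundle()].
#' @return an object of class `cohd_api`.
#' @export
bundle_api <- function(bundle) {
  stopifnot(inherits(bundle, "cohd_bundle"))
  structure(list(bundle = bundle,
                 default_dataset = names(bundle$datasets)[1L]),
            class = "cohd_api")
}

api_error <- function(status, msg, ...) {
  list(status = as.integer(status), error = sprintf(msg, ...), results = list())
}

api_ok <- function(results) {
  list(status = 200L, results = results)
}

records <- function(dt) {
  if (is.null(dt) || nrow(dt) == 0L) return(list())
  lapply(seq_len(nrow(dt)), function(i) as.list(dt[i]))
}

## prefix a dataset id column without turning a 0-row table into 1 row
with_dataset <- function(id, dt) {
  if (nrow(dt) == 0L) return(dt)
  cbind(data.table::data.table(dataset_id = id), dt)
}

get_dataset <- function(api, params) {
  id <- params$dataset_id %||% api$default_dataset
  d <- api$bundle$datasets[[id]]
  if (is.null(d)) return(NULL)
  c(d, list(dataset_id = id))
}

#' Dispatch one API request
#'
#' @param api a [bundle_api()].
#' @param endpoint endpoint path, e.g. `"/frequencies/singleConceptFreq"`.
#' @param params named list of query parameters. Common parameters:
#'   `dataset_id` (defaults to the first dataset), `q` (concept id(s) or a
#'   search string), `concept_id_1` / `concept_id_2`, `domain`, `k`.
#' @return a response list with `status` (200 for success) and `results`
#'   (list of records); error responses carry an `error` message.
#' @export
api_request <- function(api, endpoint, params = list()) {
  stopifnot(inherits(api, "cohd_api"))
  handler <- .api_handlers[[endpoint]]
  if (is.null(handler)) {
    return(api_error(404L, "unknown endpoint '%s'", endpoint))
  }
  handler(api, params)
}

#' Serialize an API response to JSON
#'
#' @param response a response from [api_request()].
#' @return a JSON string.
#' @export
api_json <- function(response) {
  jsonlite::toJSON(response, auto_unbox = TRUE, digits = NA, null = "null",
                   na = "null")
}

ep_datasets <- function(api, params) {
  out <- lapply(names(api$bundle$datasets), function(id) {
    d <- api$bundle$datasets[[id]]
    list(dataset_id = id,
         patient_count = d$patient_count,
         window_start = if (is.null(d$window)) NULL else as.character(d$window[1]),
         window_end = if (is.null(d$window)) NULL else as.character(d$window[2]))
  })
  api_ok(out)
}

ep_domain_counts <- function(api, params) {
  d <- get_dataset(api, params)
  if (is.null(d)) return(api_error(404L, "unknown dataset '%s'", params$dataset_id))
  s <- merge(d$singles, api$bundle$concepts[, .(concept_id, domain_id)],
             by = "concept_id", all.x = TRUE)
  s[is.na(domain_id), domain_id := "Unknown"]
  tab <- s[, .(count = .N), by = domain_id]
  data.table::setorder(tab, domain_id)
  api_ok(records(with_dataset(d$dataset_id, tab)))
}

ep_domain_pair_counts <- function(api, params) {
  d <- get_dataset(api, params)
  if (is.null(d)) return(api_error(404L, "unknown dataset '%s'", params$dataset_id))
  cm <- api$bundle$concepts[, .(concept_id, domain_id)]
  p <- merge(d$pairs, cm, by.x = "concept_id_1", by.y = "concept_id", all.x = TRUE)
  data.table::setnames(p, "domain_id", "domain_a")
  p <- merge(p, cm, by.x = "concept_id_2", by.y = "concept_id", all.x = TRUE)
  data.table::setnames(p, "domain_id", "domain_b")
  p[is.na(domain_a), domain_a := "Unknown"]
  p[is.na(domain_b), domain_b := "Unknown"]
  p[, `:=`(domain_1 = pmin(domain_a, domain_b),
           domain_2 = pmax(domain_a, domain_b))]
  tab <- p[, .(count = .N), by = .(domain_1, domain_2)]
  data.table::setorder(tab, domain_1, domain_2)
  api_ok(records(with_dataset(d$dataset_id, tab)))
}

ep_patient_count <- function(api, params) {
  d <- get_dataset(api, params)
  if (is.null(d)) return(api_error(404L, "unknown dataset '%s'", params$dataset_id))
  api_ok(list(list(dataset_id = d$dataset_id, patient_count = d$patient_count)))
}

ep_find_concepts <- function(api, params) {
  q <- params$q
  if (is.null(q) || !nzchar(trimws(as.character(q)))) {
    return(api_error(400L, "parameter 'q' (search string) is required"))
  }
  q <- tolower(trimws(as.character(q)))
  cd <- api$bundle$concepts
  hit <- cd[grepl(q, tolower(concept_name), fixed = TRUE)]
  if (!is.null(params$domain)) hit <- hit[domain_id == params$domain]
  if (nrow(hit) == 0L) return(api_ok(list()))
  hit <- hit[order(tolower(concept_name) != q, nchar(concept_name), concept_id)]
  api_ok(records(hit))
}

ep_concepts <- function(api, params) {
  ids <- as.integer(params$q)
  if (length(ids) == 0L) return(api_error(400L, "parameter 'q' (concept ids) is required"))
  api_ok(records(api$bundle$concepts[concept_id %in% ids]))
}

ep_vocab_unavailable <- function(api, params) {
  api_error(501L, "vocabulary not loaded: concept mapping requires an OMOP vocabulary extract")
}

ep_single_freq <- function(api, params) {
  d <- get_dataset(api, params)
  if (is.null(d)) return(api_error(404L, "unknown dataset '%s'", params$dataset_id))
  ids <- as.integer(params$q)
  if (length(ids) == 0L) return(api_error(400L, "parameter 'q' (concept ids) is required"))
  hit <- d$singles[concept_id %in% ids]
  ## absent ids yield no records; absence cannot be distinguished from
  ## privacy-based exclusion and no claim about the true count is made
  api_ok(records(with_dataset(d$dataset_id, hit)))
}

ep_paired_freq <- function(api, params) {
  d <- get_dataset(api, params)
  if (is.null(d)) return(api_error(404L, "unknown dataset '%s'", params$dataset_id))
  c1 <- as.integer(params$concept_id_1)
  c2 <- as.integer(params$concept_id_2)
  if (length(c1) != 1L || length(c2) != 1L || is.na(c1) || is.na(c2)) {
    return(api_error(400L, "concept_id_1 and concept_id_2 are required"))
  }
  lo <- min(c1, c2); hi <- max(c1, c2)
  hit <- d$pairs[concept_id_1 == lo & concept_id_2 == hi]
  api_ok(records(with_dataset(d$dataset_id, hit)))
}

ep_most_frequent <- function(api, params) {
  d <- get_dataset(api, params)
  if (is.null(d)) return(api_error(404L, "unknown dataset '%s'", params$dataset_id))
  k <- as.integer(params$k %||% 10L)
  res <- tryCatch(
    most_frequent(d$singles, concepts = api$bundle$concepts,
                  domain = params$domain, k = k),
    omopfreq_error = function(e) e
  )
  if (inherits(res, "condition")) return(api_error(400L, conditionMessage(res)))
  api_ok(records(with_dataset(d$dataset_id, res)))
}

ep_associated <- function(api, params, metric = "count") {
  d <- get_dataset(api, params)
  if (is.null(d)) return(api_error(404L, "unknown dataset '%s'", params$dataset_id))
  cid <- as.integer(params$concept_id)
  if (length(cid) != 1L || is.na(cid)) {
    return(api_error(400L, "parameter 'concept_id' is required"))
  }
  k <- as.integer(params$k %||% 10L)
  res <- tryCatch(
    top_associated(cid, d$singles, d$pairs, n_p = d$patient_count,
                   metric = params$metric %||% metric,
                   concepts = api$bundle$concepts,
                   domain = params$domain, k = k),
    omopfreq_error = function(e) e
  )
  if (inherits(res, "condition")) return(api_error(404L, conditionMessage(res)))
  api_ok(records(cbind(data.table::data.table(dataset_id = d$dataset_id,
                                              anchor_concept_id = cid), res)))
}

pair_counts_for <- function(api, params) {
  d <- get_dataset(api, params)
  if (is.null(d)) return(api_error(404L, "unknown dataset '%s'", params$dataset_id))
  c1 <- as.integer(params$concept_id_1)
  c2 <- as.integer(params$concept_id_2)
  if (length(c1) != 1L || length(c2) != 1L || is.na(c1) || is.na(c2)) {
    return(api_error(400L, "concept_id_1 and concept_id_2 are required"))
  }
  s1 <- d$singles[concept_id == c1]
  s2 <- d$singles[concept_id == c2]
  lo <- min(c1, c2); hi <- max(c1, c2)
  pp <- d$pairs[concept_id_1 == lo & concept_id_2 == hi]
  if (nrow(s1) == 0L || nrow(s2) == 0L || nrow(pp) == 0L) {
    return(api_ok(list()))
  }
  list(d = d, c1 = c1, c2 = c2, n1 = s1$count, n2 = s2$count, n12 = pp$count)
}

ep_chi_square <- function(api, params) {
  x <- pair_counts_for(api, params)
  if (!is.null(x$status)) return(x)
  res <- tryCatch(chi_square_pair(x$n12, x$n1, x$n2, x$d$patient_count),
                  omopfreq_error = function(e) e)
  if (inherits(res, "condition")) {
    return(api_error(422L, "chi-square unavailable: %s", conditionMessage(res)))
  }
  api_ok(list(list(dataset_id = x$d$dataset_id,
                   concept_id_1 = x$c1, concept_id_2 = x$c2,
                   chi_square = res$chi2, p_value = res$p_value)))
}

ep_obs_exp_ratio <- function(api, params) {
  x <- pair_counts_for(api, params)
  if (!is.null(x$status)) return(x)
  exp_ct <- expected_count(x$n1, x$n2, x$d$patient_count)
  lr <- tryCatch(log_ratio(x$n12, x$n1, x$n2, x$d$patient_count),
                 omopfreq_error = function(e) e)
  if (inherits(lr, "condition")) {
    return(api_error(422L, "log ratio unavailable: %s", conditionMessage(lr)))
  }
  api_ok(list(list(dataset_id = x$d$dataset_id,
                   concept_id_1 = x$c1, concept_id_2 = x$c2,
                   observed_count = x$n12, expected_count = exp_ct,
                   ln_ratio = lr)))
}

ep_relative_frequency <- function(api, params) {
  x <- pair_counts_for(api, params)
  if (!is.null(x$status)) return(x)
  api_ok(list(list(dataset_id = x$d$dataset_id,
                   concept_id_1 = x$c1, concept_id_2 = x$c2,
                   concept_pair_count = x$n12,
                   concept_2_count = x$n2,
                   relative_frequency = relative_frequency(x$n12, x$n2))))
}

.api_handlers <- list(
  "/metadata/datasets" = ep_datasets,
  "/metadata/domainCounts" = ep_domain_counts,
  "/metadata/domainPairCounts" = ep_domain_pair_counts,
  "/metadata/patientCount" = ep_patient_count,
  "/omop/findConceptIDs" = ep_find_concepts,
  "/omop/concepts" = ep_concepts,
  "/omop/vocabularies" = ep_vocab_unavailable,
  "/omop/mapFromStandardConceptID" = ep_vocab_unavailable,
  "/omop/mapToStandardConceptID" = ep_vocab_unavailable,
  "/frequencies/singleConceptFreq" = ep_single_freq,
  "/frequencies/pairedConceptFreq" = ep_paired_freq,
  "/frequencies/mostFrequentConcepts" = ep_most_frequent,
  "/frequencies/associatedConceptFreq" = function(api, params)
    ep_associated(api, params, metric = "count"),
  "/frequencies/associatedConceptDomainFreq" = function(api, params)
    ep_associated(api, params, metric = "count"),
  "/association/chiSquare" = ep_chi_square,
  "/association/obsExpRatio" = ep_obs_exp_ratio,
  "/association/relativeFrequency" = ep_relative_frequency
)
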