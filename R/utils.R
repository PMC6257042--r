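## Internal helpers: classed conditions, seed mixing, frequency rendering.

stop_schema <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("omopfreq_schema_error", "omopfreq_error")))
}

stop_integrity <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("omopfreq_integrity_error", "omopfreq_error")))
}

stop_value <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("omopfreq_value_error", "omopfreq_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mix a master seed with string context into a 32-bit seed
#'
#' Deterministic polynomial hash of the context strings, combined with the
#' master seed modulo 2^31 - 1. Used to give every (dataset, concept key)
#' an independent, iteration-order-free randomization stream.
#'
#' @param seed integer master seed.
#' @param ... character or numeric context components.
#' @return integer in `[0, 2^31 - 2]`.
#' @keywords internal
mix_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  ctx <- paste(vapply(list(...), function(x) paste(format(x, scientific = FALSE),
                                                   collapse = "\x1f"),
                      character(1)), collapse = "\x1f")
  h <- as.numeric(seed %% m)
  for (b in utf8ToInt(ctx)) {
    h <- (h * 131 + b) %% m
  }
  as.integer(h)
}

## Render frequencies with a fixed number of significant digits such that
## write -> read -> write round trips are byte identical. digits = NA gives
## full (17 significant digit) precision.
render_freq <- function(x, digits = 6L) {
  if (is.na(digits)) {
    out <- formatC(x, format = "g", digits = 17)
  } else {
    out <- formatC(x, format = "g", digits = digits)
  }
  trimws(out)
}

check_columns <- function(dt, required, path) {
  missing <- setdiff(required, names(dt))
  if (length(missing) > 0L) {
    stop_schema("file '%s' is missing required column(s): %s",
                path, paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

as_count_integer <- function(x, what) {
  y <- suppressWarnings(as.integer(x))
  if (anyNA(y) && !anyNA(x)) {
    stop_schema("column '%s' contains non-integer values", what)
  }
  y
}
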