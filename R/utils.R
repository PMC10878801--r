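# classed conditions so callers (and tests) can distinguish error families

pg_stop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(class = c(class, "pg_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

config_error <- function(fmt, ...) pg_stop("pg_config_error", fmt, ...)

insufficient_data_error <- function(fmt, ...) {
  pg_stop("pg_insufficient_data_error", fmt, ...)
}

check_scalar <- function(x, field, positive = FALSE, nonneg = FALSE,
                         integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    config_error("'%s' must be a single finite number", field)
  if (positive && x <= 0) config_error("'%s' must be > 0", field)
  if (nonneg && x < 0) config_error("'%s' must be >= 0", field)
  if (integerish && x != round(x)) config_error("'%s' must be an integer", field)
  invisible(x)
}

match_enum <- function(x, choices, field) {
  if (!is.character(x) || length(x) != 1L || !(x %in% choices))
    config_error("'%s' must be one of %s", field,
                 paste(sQuote(choices), collapse = ", "))
  x
}

# round-half-up, used for the SIGNAL-dot count
round_half_up <- function(x) floor(x + 0.5)

#' Derive a reproducible sub-seed from a master seed and labels
#'
#' Hashes the master seed together with an arbitrary set of labels
#' (subject id, condition, direction, ...) into an independent seed in
#' `[1, 2^31 - 2]`. The derivation is counter-free and splittable: the
#' seed of one cell never depends on which other cells exist, so adding
#' conditions or subjects to an experiment leaves all other random
#' streams untouched.
#'
#' @param master integer master seed.
#' @param ... further labels (coerced to character) identifying the stream.
#' @return A single positive integer seed.
#' @examples
#' derive_seed(1, "s01", "OPEN_LOOP", "FORWARD")
#' @export
derive_seed <- function(master, ...) {
  check_scalar(master, "master", integerish = TRUE)
  key <- paste(c(format(master, scientific = FALSE),
                 vapply(list(...), as.character, character(1))),
               collapse = "|")
  hash_seed_cpp(key)
}
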