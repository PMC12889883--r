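# Classed conditions so callers (and the CLI) can distinguish bad input
# (validation/config), broken files (parse), and filesystem failures (io).

sa_error <- function(class, message, ...) {
  stop(structure(
    class = c(class, "sa_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

sa_validation_error <- function(message, ...) {
  sa_error("sa_validation_error", message, ...)
}

sa_config_error <- function(message, ...) {
  sa_error(c("sa_config_error", "sa_validation_error"), message, ...)
}

sa_parse_error <- function(message, ...) {
  sa_error(c("sa_parse_error", "sa_validation_error"), message, ...)
}

sa_io_error <- function(message, ...) {
  sa_error("sa_io_error", message, ...)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  x <- suppressWarnings(as.numeric(x))
  if (length(x) != 1L || is.na(x) || !is.finite(x))
    sa_config_error(sprintf("'%s' must be a single finite number", name))
  if (positive && x <= 0)
    sa_config_error(sprintf("'%s' must be > 0 (got %g)", name, x))
  x
}
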