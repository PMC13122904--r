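# Structured conditions so callers (and the CLI exit-code map) can tell
# invalid input apart from an improper posterior.

stop_validation <- function(...) {
  stop(structure(
    class = c("ubr_validation_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_improper <- function(...) {
  stop(structure(
    class = c("ubr_improper_posterior", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

# scalar checks used throughout the constructors
check_scalar <- function(x, name, min = -Inf, max = Inf, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_validation(name, " must be a single non-missing number")
  if (integerish && x != round(x))
    stop_validation(name, " must be a whole number, got ", x)
  if (x < min || x > max)
    stop_validation(name, " must be in [", min, ", ", max, "], got ", x)
  invisible(x)
}
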