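#' @keywords internal
"_PACKAGE"

# Classed conditions so callers (and the CLI) can distinguish bad inputs
# (exit code 2) from numerical failures (exit code 3).

stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("cea_validation_error", "error")))
}

stop_numerical <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("cea_numerical_error", "error")))
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_validation("`%s` must be a single finite number", name)
  if (x < min || x > max)
    stop_validation("`%s` = %g outside [%g, %g]", name, x, min, max)
  invisible(x)
}

match_choice <- function(x, choices, name) {
  if (!is.character(x) || length(x) != 1L || !(x %in% choices))
    stop_validation("unknown %s '%s'; valid choices: %s",
                    name, paste(x, collapse = ","),
                    paste(choices, collapse = ", "))
  x
}
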