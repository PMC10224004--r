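# Gas constant, J mol^-1 K^-1
GAS_CONSTANT <- 8.314

# Classed conditions so callers can branch on failure mode rather than
# matching message text.
stop_partperm <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "partperm_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

warn_partperm <- function(message, class) {
  warning(warningCondition(message, class = c(class, "partperm_warning")))
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_partperm(
      sprintf("`%s` must be a single positive finite number", name),
      "partperm_domain_error"
    )
  }
  invisible(x)
}
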