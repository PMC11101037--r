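#' @keywords internal
"_PACKAGE"

# Condition helper: all package errors carry class "crmface_error" plus a
# specific subclass so callers (and tests) can match on type, not message.
crm_stop <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "crmface_error", "error")))
}

crm_assert <- function(cond, msg, class = "crm_validation_error") {
  if (!isTRUE(cond)) crm_stop(msg, class)
  invisible(TRUE)
}

# Half-up rounding to integers (base round() is round-half-even); used only
# for display of percentage tables.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x)
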