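## Shared internal helpers: classed error conditions so callers and tests can
## distinguish configuration problems from data problems.

operat_error <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "operat_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

config_error <- function(msg) operat_error(msg, "operat_config_error")
data_error   <- function(msg) operat_error(msg, "operat_data_error")
arg_error    <- function(msg) operat_error(msg, "operat_argument_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

## round half away from zero, as score tables are conventionally printed
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
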