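#' @keywords internal
"_PACKAGE"

# Classed conditions so callers (and the CLI) can distinguish bad input
# formats from violated panel/domain invariants.
abort <- function(msg, class) {
  stop(structure(
    class = c(class, "ccfdna_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

validation_error <- function(msg) abort(msg, "ccfdna_validation_error")
format_error     <- function(msg) abort(msg, "ccfdna_format_error")
input_error      <- function(msg) abort(msg, "ccfdna_input_error")

`%||%` <- function(a, b) if (is.null(a)) b else a
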