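# Condition constructors shared across the package. Every user-facing error
# carries a palsim class so callers (and the CLI wrapper) can map failures to
# exit codes without parsing messages.

pal_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "pal_error"), ...)
}

pal_unit_error <- function(message, ...) pal_abort(message, "pal_unit_error", ...)
pal_resolution_error <- function(message, ...) pal_abort(message, "pal_resolution_error", ...)
pal_cycle_error <- function(message, ...) pal_abort(message, "pal_cycle_error", ...)
pal_registration_error <- function(message, ...) pal_abort(message, "pal_registration_error", ...)
pal_execution_error <- function(message, ...) pal_abort(message, "pal_execution_error", ...)
pal_numerical_error <- function(message, ...) pal_abort(message, "pal_numerical_error", ...)
pal_io_error <- function(message, ...) pal_abort(message, "pal_io_error", ...)
pal_input_error <- function(message, ...) pal_abort(message, "pal_input_error", ...)
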