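# Classed conditions so callers (and tests) can distinguish schema problems,
# bad parameter values, and row-level data errors without parsing messages.

sb_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "sbdrive_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

sb_schema_error    <- function(msg, ...) sb_stop(msg, "sbdrive_schema_error", ...)
sb_row_error       <- function(msg, rows = NULL) sb_stop(msg, "sbdrive_row_error", rows = rows)
sb_validation_error <- function(msg, ...) sb_stop(msg, "sbdrive_validation_error", ...)
sb_parameter_error <- function(msg, ...) sb_stop(msg, "sbdrive_parameter_error", ...)
sb_input_error     <- function(msg, ...) sb_stop(msg, "sbdrive_input_error", ...)
sb_io_error        <- function(msg, ...) sb_stop(msg, "sbdrive_io_error", ...)
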