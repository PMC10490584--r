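# Classed conditions so callers (and the CLI) can map failure modes to
# distinct exit codes.

stop_cr <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "cardioresp_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_invalid <- function(msg, ...) stop_cr("cardioresp_invalid_parameter", msg, ...)
stop_degenerate <- function(msg, ...) stop_cr("cardioresp_degenerate_input", msg, ...)
stop_estimation <- function(msg, ...) stop_cr("cardioresp_estimation_failure", msg, ...)
stop_format <- function(msg, ...) stop_cr("cardioresp_format_error", msg, ...)
stop_io <- function(msg, ...) stop_cr("cardioresp_io_error", msg, ...)
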