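# Classed conditions so the CLI can map failures onto distinct exit codes:
# usage (1), parse/format (2), capacity (3), I/O (4). Library callers can
# handle them with tryCatch() on the subclass.

stop_with <- function(subclass, message, call = sys.call(-1)) {
  stop(structure(
    list(message = message, call = call),
    class = c(subclass, "mafkmer_error", "error", "condition")
  ))
}

stop_usage <- function(message) stop_with("mafkmer_usage_error", message)

stop_parse <- function(message) stop_with("mafkmer_parse_error", message)

stop_capacity <- function(message) stop_with("mafkmer_capacity_error", message)

stop_io <- function(message) stop_with("mafkmer_io_error", message)

stop_arg <- function(message) stop_with("mafkmer_argument_error", message)
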