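# Classed conditions so callers (and the CLI) can map failures to exit codes.

tp2w_abort <- function(message, class, ...) {
  stop(structure(
    class = c(class, "tp2w_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

abort_parse <- function(message, ...) tp2w_abort(message, "tp2w_parse_error", ...)
abort_validation <- function(message, ...) tp2w_abort(message, "tp2w_validation_error", ...)
abort_lookup <- function(message, ...) tp2w_abort(message, "tp2w_lookup_error", ...)
abort_usage <- function(message, ...) tp2w_abort(message, "tp2w_usage_error", ...)

tp2w_warn <- function(message, class = "tp2w_warning") {
  warning(warningCondition(message, class = class))
}
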