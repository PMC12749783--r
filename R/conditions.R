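# Classed error conditions so callers and tests can catch specific failure
# modes (e.g. tonescale_degenerate_chromaticity) instead of matching messages.

stop_tonescale <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(
    message,
    class = c(paste0("tonescale_", class), "tonescale_error", "error", "condition"),
    call = call
  ))
}

warn_tonescale <- function(message, class) {
  warning(warningCondition(
    message,
    class = c(paste0("tonescale_", class), "tonescale_warning", "warning", "condition")
  ))
}
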