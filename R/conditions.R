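# Structured conditions: every error/warning raised by the package carries a
# class "dcaps_<tag>" so callers (and the CLI) can branch without regexes.

dcaps_error <- function(tag, message, ...) {
  structure(
    class = c(paste0("dcaps_", tag), "dcaps_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
}

dcaps_warning <- function(tag, message, ...) {
  structure(
    class = c(paste0("dcaps_", tag), "dcaps_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
}

stop_dcaps <- function(tag, fmt, ...) stop(dcaps_error(tag, sprintf(fmt, ...)))
warn_dcaps <- function(tag, fmt, ...) warning(dcaps_warning(tag, sprintf(fmt, ...)))
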