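# Classed conditions so callers (pipeline, tests) can react to specific
# failure modes without parsing message strings.

ufe_error <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "pcaufe_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

ufe_warning <- function(message, class) {
  warning(structure(
    class = c(class, "pcaufe_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}
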