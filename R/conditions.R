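# Classed conditions so callers (and tests) can distinguish failure modes.

abort_oct <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "octbias_error"), call = call))
}

warn_oct <- function(message, class) {
  warning(warningCondition(message, class = c(class, "octbias_warning")))
}
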