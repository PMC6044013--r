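# Classed conditions so callers (and the CLI) can branch on error families.

bfx_error <- function(message, class, data = list()) {
  cond <- structure(
    class = c(class, "batchfx_error", "error", "condition"),
    c(list(message = message, call = sys.call(-1)), data)
  )
  stop(cond)
}

bfx_warning <- function(message, class) {
  warning(warningCondition(message, class = c(class, "batchfx_warning")))
}
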