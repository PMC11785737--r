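# Classed error conditions so callers (and the CLI) can distinguish
# configuration, data, geometry and protocol failures.
stop_fm <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("fm_", class, "_error"), "fm_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)))
}
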