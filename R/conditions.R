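# Classed conditions so callers (and the CLI) can distinguish bad input
# (exit 2) from statistically degenerate input (exit 3).

stop_validation <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("csi_validation_error", "csi_error")))
}

stop_degenerate <- function(msg) {
  stop(errorCondition(msg, class = c("csi_degenerate_error", "csi_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
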