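# Classed conditions so callers (and tests) can distinguish failure modes.
hemi_stop <- function(class, fmt, ...) {
  msg <- if (length(list(...))) sprintf(fmt, ...) else fmt
  stop(structure(
    class = c(class, "hemilat_error", "error", "condition"),
    list(message = msg, call = sys.call(-1L))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
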