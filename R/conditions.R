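# Classed error conditions so callers (and the CLI) can react to specific
# failure modes instead of matching message strings.

stop_segmoment <- function(msg, class, call = sys.call(-1)) {
  cond <- structure(
    class = c(class, "segmoment_error", "error", "condition"),
    list(message = msg, call = call)
  )
  stop(cond)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

check_finite_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_segmoment(sprintf("'%s' must be a single finite number", name),
                   "segmoment_invalid_input")
  }
  invisible(x)
}

check_planar_point <- function(p, name) {
  if (!is.numeric(p) || length(p) != 2L || !all(is.finite(p))) {
    stop_segmoment(sprintf("'%s' must be a finite numeric (x, y) pair in cm", name),
                   "segmoment_invalid_input")
  }
  invisible(as.numeric(p))
}
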