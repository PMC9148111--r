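# Classed conditions so callers can distinguish bad arguments from
# geometric failures (out-of-field rays, degenerate corners, ...).

stop_fisheye <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "fisheyetree_error", "error")))
}

check_number <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_fisheye(sprintf("`%s` must be a single number", name),
                 "fisheyetree_invalid_argument")
  }
  if (finite && !is.finite(x)) {
    stop_fisheye(sprintf("`%s` must be finite", name),
                 "fisheyetree_invalid_argument")
  }
  if (positive && x <= 0) {
    stop_fisheye(sprintf("`%s` must be > 0 (got %g)", name, x),
                 "fisheyetree_invalid_argument")
  }
  invisible(x)
}
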