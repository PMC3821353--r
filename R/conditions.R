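#' @keywords internal
#' Classed error helper: every user-facing failure mode gets a stable
#' condition class ("veinpwm_<kind>") so callers and tests can catch it.
vp_stop <- function(kind, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(paste0("veinpwm_", kind), "veinpwm_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

vp_warn <- function(kind, msg) {
  warning(structure(
    class = c(paste0("veinpwm_", kind), "veinpwm_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
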