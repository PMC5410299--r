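#' Signed fold-change convention
#'
#' Convert a linear case/control ratio `r` to the signed fold-change (FC)
#' convention used throughout the package: `r` when `r >= 1`, `-1/r`
#' otherwise, so `|FC| >= 1` always and down-regulation carries a negative
#' sign.
#'
#' @param ratio positive linear ratio(s), case over control.
#' @return numeric vector of signed fold changes.
#' @export
signed_ratio <- function(ratio) {
  stopifnot(is.numeric(ratio), all(ratio > 0))
  ifelse(ratio >= 1, ratio, -1 / ratio)
}

# internal: abort with a classed condition so tests can assert on error class
abort_lncnet <- function(msg, class) {
  stop(structure(
    class = c(class, "lncnet_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

input_error  <- function(msg) abort_lncnet(msg, "lncnet_input_error")
config_error <- function(msg) abort_lncnet(msg, "lncnet_config_error")
state_error  <- function(msg) abort_lncnet(msg, "lncnet_state_error")
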