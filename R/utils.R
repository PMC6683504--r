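# Internal helpers shared across modules.

rd_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "rd_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' @noRd
check_numeric <- function(x, name, lower = -Inf, upper = Inf, finite = TRUE) {
  if (!is.numeric(x)) rd_stop(sprintf("`%s` must be numeric", name), "rd_value_error")
  if (finite && any(!is.finite(x))) {
    rd_stop(sprintf("`%s` contains non-finite values", name), "rd_value_error")
  }
  if (any(x < lower, na.rm = TRUE) || any(x > upper, na.rm = TRUE)) {
    rd_stop(sprintf("`%s` must lie in [%s, %s]", name, lower, upper), "rd_value_error")
  }
  invisible(x)
}

# Constants used throughout: the two trial timepoints, the variant-class
# vocabulary, the ordered copy-number states and the risk strata.
TIMEPOINTS <- c("DIAGNOSIS", "SURGERY")
VARIANT_CLASSES <- c("MISSENSE", "NONSENSE", "FRAMESHIFT", "INFRAME_INDEL", "SPLICE", "OTHER")
CN_STATES <- c("EXTENSIVE_LOSS", "LOSS", "NORMAL", "GAIN", "AMPLIFIED")
RISK_STRATA <- c("LOW", "MODERATE", "HIGH")

#' Ordered copy-number state factor
#' @param x character vector of state labels
#' @return ordered factor with levels EXTENSIVE_LOSS < LOSS < NORMAL < GAIN < AMPLIFIED
#' @export
cn_state_factor <- function(x) {
  factor(x, levels = CN_STATES, ordered = TRUE)
}
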