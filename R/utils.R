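#' @keywords internal
#' @useDynLib gvitgp, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Condition helpers: every user-facing failure carries a subclass so callers
# (and the test suite) can distinguish contract violations from bugs.
gv_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "gvitgp_error", "error", "condition")))
}

gv_format_error  <- function(msg) gv_stop(msg, "gvitgp_format_error")
gv_validation_error <- function(msg) gv_stop(msg, "gvitgp_validation_error")
gv_config_error  <- function(msg) gv_stop(msg, "gvitgp_config_error")
gv_contract_error <- function(msg) gv_stop(msg, "gvitgp_contract_error")
gv_leakage_error <- function(msg) gv_stop(msg, "gvitgp_leakage_error")
gv_numeric_error <- function(msg) gv_stop(msg, "gvitgp_numeric_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic child seed derivation; keeps results inside 32-bit range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 2654435761 + offset) %% 2147483647)
}
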