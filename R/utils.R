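#' @keywords internal
"_PACKAGE"

# Classed conditions so callers (and the CLI) can distinguish user/config
# errors from numerical failures.
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("apahtp_config_error", "error")))
}

stop_arg <- function(...) {
  stop(errorCondition(paste0(...), class = c("apahtp_argument_error", "error")))
}

stop_shape <- function(...) {
  stop(errorCondition(paste0(...), class = c("apahtp_shape_error", "error")))
}

stop_degenerate <- function(...) {
  stop(errorCondition(paste0(...), class = c("apahtp_degenerate_error", "error")))
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("apahtp_format_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Squared 3-component complex magnitude per row of an M x 3 complex matrix.
vec_mag2 <- function(E3) {
  rowSums(Mod(E3)^2)
}
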