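#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a classed condition
#' @noRd
fw_stop <- function(msg, class, call. = FALSE) {
  cond <- structure(
    class = c(class, "fwtrace_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  )
  stop(cond)
}

#' Check a scalar numeric argument
#' @noRd
check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    fw_stop(sprintf("`%s` must be a single finite number in [%s, %s]", name,
                    format(lower), format(upper)), "fwtrace_config_error")
  }
  invisible(x)
}

#' z-score a vector, guarding zero variance
#' @noRd
zscore <- function(x) {
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(x - mean(x, na.rm = TRUE))
  (x - mean(x, na.rm = TRUE)) / s
}

#' Derive a 32-bit sub-seed from a base seed and a stream label
#' @noRd
sub_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 69069 + h) %% 2147483647)
}
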