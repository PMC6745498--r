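#' Structured error conditions
#'
#' All user-facing failures are signalled as classed conditions so callers
#' (and the pipeline driver) can distinguish configuration errors, data
#' errors, per-curve landmark failures and degenerate numerical cases.
#'
#' @section Condition classes:
#' * `placentaq_config_error` — invalid parameters or configuration.
#' * `placentaq_data_error` — malformed or inconsistent input data.
#' * `placentaq_pipeline_error` — a whole pipeline stage failed.
#' * `placentaq_landmark_error` — a curve has no usable landmark structure;
#'   subclasses `placentaq_no_first_maximum` and `placentaq_no_recovery_limb`.
#' * `placentaq_degenerate_error` — a ratio or scaling denominator is zero.
#'
#' @name placentaq-conditions
#' @keywords internal
NULL

abort_with <- function(class, message, ...) {
  stop(structure(
    class = c(class, "placentaq_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

abort_config <- function(message, ...) {
  abort_with("placentaq_config_error", message, ...)
}

abort_data <- function(message, ...) {
  abort_with("placentaq_data_error", message, ...)
}

abort_pipeline <- function(message, ...) {
  abort_with("placentaq_pipeline_error", message, ...)
}

abort_degenerate <- function(message, ...) {
  abort_with("placentaq_degenerate_error", message, ...)
}

abort_no_first_maximum <- function(message, ...) {
  abort_with(c("placentaq_no_first_maximum", "placentaq_landmark_error"),
             message, ...)
}

abort_no_recovery_limb <- function(message, ...) {
  abort_with(c("placentaq_no_recovery_limb", "placentaq_landmark_error"),
             message, ...)
}

# argument checking helpers ---------------------------------------------

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_config(sprintf("`%s` must be a single finite number", name))
  }
  ok_lo <- if (strict_lower) x > lower else x >= lower
  ok_hi <- if (strict_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi) {
    abort_config(sprintf(
      "`%s` = %g is outside the allowed range %s%g, %g%s",
      name, x,
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]"
    ))
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < lower) {
    abort_config(sprintf("`%s` must be an integer >= %d", name, lower))
  }
  invisible(as.integer(x))
}
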