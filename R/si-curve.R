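#' Signal-intensity time series for one region of interest
#'
#' An `si_curve` holds the mean signal intensity (SI) of one placenta (or of
#' the vena cava, used as a scaling reference) at each timepoint of a dynamic
#' contrast-enhanced MRI acquisition. Times are in seconds and must be
#' strictly increasing; SI values are non-negative and on an arbitrary
#' scanner scale. Curves produced by [simulate_si_curve()] additionally carry
#' a `truth` element with the noiseless ground-truth landmark ratios.
#'
#' @param times Numeric vector of acquisition times in seconds, strictly
#'   increasing, length >= 3.
#' @param values Numeric vector of mean SI values, same length as `times`,
#'   finite and non-negative.
#' @param id Identifier of the placenta / ROI.
#' @param group Group label (genotype), or `NA`.
#' @param truth Optional list of ground-truth quantities for simulated
#'   curves (see [simulate_si_curve()]).
#'
#' @return An object of class `si_curve`: a list with elements `times`,
#'   `values`, `id`, `group` and optionally `truth`.
#' @examples
#' curve <- si_curve(times = c(163, 326, 489), values = c(100, 150, 120),
#'                   id = "pl1", group = "WT")
#' curve
#' @export
si_curve <- function(times, values, id = "roi", group = NA_character_,
                     truth = NULL) {
  if (!is.numeric(times) || !is.numeric(values)) {
    abort_data("`times` and `values` must be numeric")
  }
  if (length(times) != length(values)) {
    abort_data(sprintf("length mismatch: %d times vs %d values",
                       length(times), length(values)))
  }
  if (length(times) < 3L) {
    abort_data("an SI curve needs at least 3 timepoints")
  }
  if (anyNA(times) || anyNA(values) || !all(is.finite(values))) {
    abort_data("times and values must be finite and non-missing")
  }
  if (any(diff(times) <= 0)) {
    bad <- which(diff(times) <= 0)[1L] + 1L
    abort_data(sprintf("times must be strictly increasing (violation at timepoint %d)", bad))
  }
  if (any(values < 0)) {
    abort_data("SI values must be non-negative")
  }
  structure(
    list(times = as.numeric(times), values = as.numeric(values),
         id = as.character(id), group = as.character(group), truth = truth),
    class = "si_curve"
  )
}

#' @export
print.si_curve <- function(x, ...) {
  cat(sprintf("<si_curve> id=%s group=%s, %d timepoints over %.1f min\n",
              x$id, x$group, length(x$times),
              (x$times[length(x$times)] - 0) / 60))
  cat(sprintf("  SI range [%.3g, %.3g]\n", min(x$values), max(x$values)))
  if (!is.null(x$truth)) {
    cat(sprintf("  ground truth: E=%.4f R=%.4f\n",
                x$truth$initial_enhancement, x$truth$recovery))
  }
  invisible(x)
}

#' @export
length.si_curve <- function(x) length(x$times)
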