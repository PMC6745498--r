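#' One microscope field of counted syncytia
#'
#' Each syncytium is represented by the positivity flags (0/1) of its
#' nuclei, as counted on DAB-stained sections restricted to the
#' syncytiotrophoblast.
#'
#' @param field_id Field identifier.
#' @param syncytia List with one element per syncytium, each a vector of
#'   binary nucleus positivity flags (>= 1 nucleus each).
#' @return An object of class `syncytia_field`.
#' @examples
#' syncytia_field("f1", list(c(0, 1), c(0, 0), c(1, 1, 1)))
#' @export
syncytia_field <- function(field_id, syncytia) {
  if (!is.list(syncytia) || length(syncytia) == 0L) {
    abort_data("a field must contain at least one syncytium")
  }
  for (i in seq_along(syncytia)) {
    s <- syncytia[[i]]
    if (length(s) == 0L) {
      abort_data(sprintf("syncytium %d has no nuclei", i))
    }
    if (!all(s %in% c(0, 1))) {
      abort_data(sprintf("syncytium %d has non-binary positivity flags", i))
    }
  }
  structure(
    list(field_id = as.character(field_id),
         syncytia = lapply(syncytia, as.integer)),
    class = "syncytia_field"
  )
}

#' @export
print.syncytia_field <- function(x, ...) {
  cat(sprintf("<syncytia_field> %s: %d syncytia, %d nuclei, %.1f%% positive syncytia\n",
              x$field_id, length(x$syncytia),
              sum(lengths(x$syncytia)), percent_positive_syncytia(x)))
  invisible(x)
}

#' Percent positive syncytia in a field
#'
#' A syncytium counts as positive when it contains one or more positive
#' (DAB-stained) nuclei; the statistic is the percentage of positive
#' syncytia out of all syncytia counted in the field.
#'
#' @param field A [syncytia_field()].
#' @return Percentage in `[0, 100]`.
#' @examples
#' f <- syncytia_field("f1", list(c(0, 1), c(0, 0), c(0, 0), c(0, 0)))
#' percent_positive_syncytia(f) # 25
#' @export
percent_positive_syncytia <- function(field) {
  if (!inherits(field, "syncytia_field")) {
    abort_data("`field` must be a syncytia_field")
  }
  pos <- vapply(field$syncytia, function(s) any(s == 1L), logical(1))
  100 * sum(pos) / length(pos)
}

#' Aggregate per-field percentages into a mean and SEM
#'
#' Counting protocols call for at least 12 fields of view per specimen; with
#' fewer fields the aggregate is still computed but a warning is emitted,
#' since the minimum is a study-design guideline rather than a mathematical
#' precondition.
#'
#' @param percentages Numeric vector of per-field values.
#' @param min_fields Number of fields below which to warn (default 12).
#' @return List with `mean`, `sem` and `n_fields`.
#' @examples
#' aggregate_fields(c(25, 30, 20, 25, 35, 25, 30, 20, 25, 25, 30, 20))
#' @export
aggregate_fields <- function(percentages, min_fields = 12) {
  if (length(percentages) == 0L || anyNA(percentages)) {
    abort_data("`percentages` must be a non-empty vector without missing values")
  }
  if (length(percentages) < min_fields) {
    warning(sprintf("only %d counting fields (fewer than the recommended %d)",
                    length(percentages), min_fields), call. = FALSE)
  }
  list(mean = mean(percentages), sem = sem(percentages),
       n_fields = length(percentages))
}

# Rubric bins: left-closed / right-open, except the top seam where "more
# than 75%" is strict, so exactly 75% falls in the 3.5 bin.
ki67_rubric <- data.frame(
  lower = c(0, 0.05, 0.10, 0.25, 0.33, 0.50, 0.66),
  upper = c(0.05, 0.10, 0.25, 0.33, 0.50, 0.66, 0.75),
  score = c(0.5, 1, 1.5, 2, 2.5, 3, 3.5)
)

#' Semi-quantitative Ki67 proliferation score
#'
#' Maps the fraction of Ki67-positive trophoblasts in a field to the
#' nine-level 0-4 rubric (0.5 intervals): 0 = negative staining, 0.5 = under
#' 5% positive, 1 = 5-10%, 1.5 = 10-25%, 2 = 25-33%, 2.5 = 33-50%,
#' 3 = 50-66%, 3.5 = 66-75%, and 4 = more than 75%. Printed ranges are read
#' as left-closed/right-open; because "more than 75%" is the rubric's only
#' strict wording, exactly 75% scores 3.5. A fraction of exactly 0 scores 0
#' (negative staining) and any positive fraction below 5% scores 0.5, which
#' makes the scale exhaustive over `[0, 1]`.
#'
#' @param fraction_positive Fraction of positive trophoblasts, in `[0, 1]`.
#'   Vectorised.
#' @return Score(s) on the scale `{0, 0.5, 1, ..., 4}`.
#' @examples
#' ki67_score(c(0, 0.03, 0.30, 0.70, 0.80))
#' @export
ki67_score <- function(fraction_positive) {
  if (!is.numeric(fraction_positive) || length(fraction_positive) == 0L ||
      anyNA(fraction_positive) ||
      any(fraction_positive < 0 | fraction_positive > 1)) {
    abort_data("`fraction_positive` must be numeric in [0, 1]")
  }
  vapply(fraction_positive, function(f) {
    if (f == 0) return(0)
    if (f > 0.75) return(4)
    hit <- which(f >= ki67_rubric$lower & f < ki67_rubric$upper)
    if (length(hit) == 0L) return(3.5) # f == 0.75 exactly
    ki67_rubric$score[hit[1L]]
  }, numeric(1))
}

#' Trophoblast fusion index
#'
#' Quantifies syncytialisation of a trophoblast culture from the per-cell
#' nucleus counts. Two definitions are supported:
#' \describe{
#'   \item{`"nuclei"` (default)}{percentage of all nuclei that reside in
#'     multinucleated (fused, >= 2 nuclei) cells. This weights large
#'     syncytia by their size and tracks the fraction of the culture's
#'     nuclear material that has fused.}
#'   \item{`"cells"`}{percentage of cells that are multinucleated.}
#' }
#'
#' @param nucleus_counts Integer vector: nuclei per cell (each >= 1).
#' @param definition `"nuclei"` or `"cells"`.
#' @return Percentage in `[0, 100]`.
#' @examples
#' fusion_index(c(1, 2))                       # 66.7 (2 of 3 nuclei fused)
#' fusion_index(c(1, 2), definition = "cells") # 50
#' @export
fusion_index <- function(nucleus_counts, definition = c("nuclei", "cells")) {
  definition <- match.arg(definition)
  if (!is.numeric(nucleus_counts) || length(nucleus_counts) == 0L ||
      anyNA(nucleus_counts) || any(nucleus_counts < 1) ||
      any(nucleus_counts != round(nucleus_counts))) {
    abort_data("`nucleus_counts` must be integers >= 1, one per cell")
  }
  fused <- nucleus_counts >= 2
  if (definition == "nuclei") {
    100 * sum(nucleus_counts[fused]) / sum(nucleus_counts)
  } else {
    100 * sum(fused) / length(nucleus_counts)
  }
}

#' Single-channel intensity image
#'
#' @param pixels Numeric matrix of finite, non-negative intensities.
#' @param mask Optional logical/0-1 matrix of the same shape selecting the
#'   tissue region; must select at least one pixel.
#' @param channel Semantics label, e.g. `"SA-b-gal"` or `"gelatinolysis"`.
#' @return An object of class `intensity_image`.
#' @export
intensity_image <- function(pixels, mask = NULL, channel = "SA-b-gal") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort_data("`pixels` must be a numeric matrix")
  }
  if (anyNA(pixels) || any(!is.finite(pixels))) {
    abort_data("pixel intensities must be finite")
  }
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(pixels))) {
      abort_data("mask shape does not match the image")
    }
    mask <- matrix(as.logical(mask), nrow = nrow(pixels))
    if (anyNA(mask)) abort_data("mask contains missing values")
    if (!any(mask)) abort_data("mask selects no pixels")
  }
  structure(list(pixels = pixels, mask = mask, channel = channel),
            class = "intensity_image")
}

#' @export
print.intensity_image <- function(x, ...) {
  cat(sprintf("<intensity_image> %dx%d px, channel=%s%s\n",
              nrow(x$pixels), ncol(x$pixels), x$channel,
              if (is.null(x$mask)) "" else
                sprintf(", mask covers %.1f%%", 100 * mean(x$mask))))
  invisible(x)
}

#' Area-fraction and mean-intensity quantification of a staining image
#'
#' Quantifies a staining or activity image (SA-beta-gal histochemistry, in
#' situ gelatin zymography) the way an ImageJ-style analysis does: the area
#' fraction is the proportion of (masked) pixels whose intensity exceeds a
#' threshold, and the mean intensity is the plain mean over the (masked)
#' pixels. The default threshold is Otsu's method on the masked histogram —
#' deterministic and parameter-free; a fixed numeric threshold may be given
#' instead.
#'
#' @param image An [intensity_image()].
#' @param threshold `"otsu"` (default) or a single numeric threshold.
#' @return List with `area_fraction`, `mean_intensity` and the `threshold`
#'   used.
#' @examples
#' img <- intensity_image(matrix(c(0, 0, 1, 1), 2))
#' quantify_intensity(img, threshold = 0.5)
#' @export
quantify_intensity <- function(image, threshold = "otsu") {
  if (!inherits(image, "intensity_image")) {
    abort_data("`image` must be an intensity_image")
  }
  vals <- if (is.null(image$mask)) as.vector(image$pixels) else
    image$pixels[image$mask]
  if (identical(threshold, "otsu")) {
    rng <- range(vals)
    if (rng[1L] == rng[2L]) {
      warning("constant image: Otsu threshold undefined, reporting area fraction 0",
              call. = FALSE)
      thr <- rng[2L]
    } else {
      thr <- EBImage::otsu(EBImage::Image(matrix(vals, nrow = 1L)),
                           range = rng)
    }
  } else {
    thr <- check_number(threshold, "threshold")
  }
  list(area_fraction = mean(vals > thr),
       mean_intensity = mean(vals),
       threshold = as.numeric(thr))
}

#' Fold change between two groups of quantities
#'
#' Ratio of group means, `mean(group_a) / mean(group_b)`. When the ratio is
#' below 1 it is additionally reported as an x-fold *reduction* (the
#' reciprocal), matching how decreases in staining or activity are usually
#' stated.
#'
#' @param group_a,group_b Non-empty numeric vectors; `mean(group_b)` must be
#'   positive.
#' @return List with `ratio` (A over B), `fold` (>= 1) and `direction`
#'   (`"increase"`, `"reduction"` or `"none"`).
#' @examples
#' group_fold_change(c(9, 11), c(30, 36.4)) # ~3.32-fold reduction
#' @export
group_fold_change <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L ||
      anyNA(group_a) || anyNA(group_b)) {
    abort_data("both groups must be non-empty without missing values")
  }
  mb <- mean(group_b)
  if (mb <= 0) {
    abort_degenerate("mean of the reference group must be positive")
  }
  ratio <- mean(group_a) / mb
  if (ratio == 1) {
    list(ratio = 1, fold = 1, direction = "none")
  } else if (ratio < 1) {
    list(ratio = ratio, fold = 1 / ratio, direction = "reduction")
  } else {
    list(ratio = ratio, fold = ratio, direction = "increase")
  }
}
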