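#' Simulate microscope fields of syncytia with nucleus positivity
#'
#' Emulates the counting structure of DAB-stained placental sections: each
#' field contains a fixed number of syncytia, each syncytium one or more
#' nuclei, and each nucleus is positive independently with probability
#' `p_nucleus_positive` (a Bernoulli staining model). The per-field count of
#' syncytia containing at least one positive nucleus — the quantity the
#' percent-positive statistic measures — is recorded as ground truth on each
#' field.
#'
#' @param n_fields Number of fields (>= 1).
#' @param syncytia_per_field Syncytia in every field (>= 1).
#' @param nuclei_per_syncytium Either a single count, a length-2 vector
#'   `c(min, max)` sampled uniformly, or a function `f(n)` returning `n`
#'   counts (all >= 1).
#' @param p_nucleus_positive Per-nucleus positivity probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return List of [syncytia_field()] objects; each carries a
#'   `truth` attribute with `n_positive_syncytia`.
#' @examples
#' fields <- simulate_syncytia_fields(3, 10, c(2, 8), 0.3, seed = 1)
#' attr(fields[[1]], "truth")
#' @export
simulate_syncytia_fields <- function(n_fields, syncytia_per_field,
                                     nuclei_per_syncytium = c(2, 12),
                                     p_nucleus_positive = 0.5, seed = 1) {
  n_fields <- check_count(n_fields, "n_fields")
  syncytia_per_field <- check_count(syncytia_per_field, "syncytia_per_field")
  check_number(p_nucleus_positive, "p_nucleus_positive", lower = 0, upper = 1)
  draw_counts <- nuclei_count_sampler(nuclei_per_syncytium)
  lapply(seq_len(n_fields), function(fi) {
    with_local_seed(sub_seed(seed, fi), {
      counts <- draw_counts(syncytia_per_field)
      if (any(counts < 1)) {
        abort_config("nuclei_per_syncytium must produce counts >= 1")
      }
      syncytia <- lapply(counts, function(m) {
        as.integer(stats::runif(m) < p_nucleus_positive)
      })
      field <- syncytia_field(sprintf("field_%d", fi), syncytia)
      attr(field, "truth") <- list(
        n_positive_syncytia = sum(vapply(syncytia, function(s) any(s == 1L),
                                         logical(1)))
      )
      field
    })
  })
}

nuclei_count_sampler <- function(spec) {
  if (is.function(spec)) {
    return(spec)
  }
  if (is.numeric(spec) && length(spec) == 1L) {
    m <- check_count(spec, "nuclei_per_syncytium")
    return(function(n) rep(m, n))
  }
  if (is.numeric(spec) && length(spec) == 2L) {
    lo <- check_count(spec[1L], "nuclei_per_syncytium[1]")
    hi <- check_count(spec[2L], "nuclei_per_syncytium[2]")
    if (hi < lo) abort_config("nuclei_per_syncytium range must have min <= max")
    return(function(n) sample(lo:hi, n, replace = TRUE))
  }
  abort_config("`nuclei_per_syncytium` must be a count, a c(min, max) range, or a function")
}

#' Simulate a single-channel staining / activity image
#'
#' Emulates a quantifiable histochemistry image (SA-beta-gal staining or in
#' situ gelatin zymography): exactly `round(positive_fraction * n_pixels)`
#' pixels are set to the foreground level before noise, the rest to the
#' background level, positions chosen uniformly at random; Gaussian noise is
#' then added per pixel. Intensities use a `[0, 1]` convention so images
#' round-trip through standard image files.
#'
#' @param shape Length-2 integer vector, image height and width in pixels.
#' @param positive_fraction Planted fraction of foreground pixels in `[0, 1]`.
#' @param fg_level,bg_level Foreground / background intensity,
#'   `fg_level > bg_level`.
#' @param noise_sd Per-pixel Gaussian noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @param channel Semantics label stored on the image.
#' @return An [intensity_image()]; its `truth` attribute records the exact
#'   planted `positive_fraction` (after rounding to whole pixels).
#' @examples
#' img <- simulate_intensity_image(c(64, 64), 0.25, seed = 3)
#' attr(img, "truth")$positive_fraction
#' @export
simulate_intensity_image <- function(shape = c(128, 128), positive_fraction,
                                     fg_level = 0.8, bg_level = 0.2,
                                     noise_sd = 0.02, seed = 1,
                                     channel = "SA-b-gal") {
  if (length(shape) != 2L) abort_config("`shape` must have two elements")
  nr <- check_count(shape[1L], "shape[1]")
  nc <- check_count(shape[2L], "shape[2]")
  check_number(positive_fraction, "positive_fraction", lower = 0, upper = 1)
  check_number(fg_level, "fg_level")
  check_number(bg_level, "bg_level")
  check_number(noise_sd, "noise_sd", lower = 0)
  if (fg_level <= bg_level) {
    abort_config("`fg_level` must be strictly greater than `bg_level`")
  }
  n_pix <- nr * nc
  n_pos <- round(positive_fraction * n_pix)
  px <- with_local_seed(seed, {
    m <- matrix(bg_level, nrow = nr, ncol = nc)
    if (n_pos > 0) m[sample.int(n_pix, n_pos)] <- fg_level
    m + matrix(stats::rnorm(n_pix, 0, noise_sd), nr, nc)
  })
  img <- intensity_image(px, channel = channel)
  attr(img, "truth") <- list(positive_fraction = n_pos / n_pix,
                             n_positive = n_pos)
  img
}
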