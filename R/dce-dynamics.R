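#' Extract a mean-SI time series from a volume series and ROI masks
#'
#' The region of interest of a placenta is outlined per scan (masks may
#' differ between timepoints when the fetus moved); the curve value at
#' timepoint `k` is the arithmetic mean of the voxels inside mask `k`.
#'
#' @param volumes Numeric array whose last dimension is time; each
#'   `volumes[..., k]` is the signal volume of scan `k`.
#' @param masks Either one logical/0-1 array matching a single volume
#'   (reused at every timepoint) or a list with one such mask per timepoint.
#'   Every mask must be non-empty.
#' @param times Acquisition times in seconds, or a [scan_schedule()] whose
#'   length matches the series.
#' @param id,group Identifier and group label for the resulting curve.
#' @return An [si_curve()].
#' @examples
#' vol <- array(rep(1:4, each = 8), dim = c(2, 2, 2, 4))
#' mask <- array(TRUE, dim = c(2, 2, 2))
#' extract_roi_timeseries(vol, mask, times = c(163, 326, 489, 652))
#' @export
extract_roi_timeseries <- function(volumes, masks, times, id = "roi",
                                   group = NA_character_) {
  if (!is.array(volumes) || length(dim(volumes)) < 2L) {
    abort_data("`volumes` must be an array with time as its last dimension")
  }
  dims <- dim(volumes)
  n_t <- dims[length(dims)]
  vol_dim <- dims[-length(dims)]
  if (inherits(times, "scan_schedule")) times <- times$times
  if (length(times) != n_t) {
    abort_data(sprintf("%d timepoints in the volume series but %d times given",
                       n_t, length(times)))
  }
  if (!is.list(masks)) masks <- rep(list(masks), n_t)
  if (length(masks) != n_t) {
    abort_data(sprintf("%d masks given for %d timepoints", length(masks), n_t))
  }
  flat <- matrix(volumes, nrow = prod(vol_dim), ncol = n_t)
  values <- vapply(seq_len(n_t), function(k) {
    m <- masks[[k]]
    if (!identical(as.integer(dim(m)), as.integer(vol_dim))) {
      abort_data(sprintf("mask %d does not match the volume dimensions", k))
    }
    sel <- as.logical(m)
    if (anyNA(sel)) abort_data(sprintf("mask %d contains missing values", k))
    if (!any(sel)) abort_data(sprintf("mask at timepoint %d is empty", k))
    mean(flat[sel, k])
  }, numeric(1))
  si_curve(times = times, values = values, id = id, group = group)
}

#' Landmark indices of a biphasic SI curve
#'
#' @param first_max,interior_min,second_max 1-based indices into the curve:
#'   the first interior local maximum, the minimum between the two maxima,
#'   and the second maximum (the final timepoint is eligible). Must satisfy
#'   `1 < first_max < interior_min < second_max <= n`.
#' @param n Curve length the indices refer to.
#' @return An object of class `si_landmarks`.
#' @seealso [detect_landmarks()]
#' @export
si_landmarks <- function(first_max, interior_min, second_max, n) {
  first_max <- check_count(first_max, "first_max")
  interior_min <- check_count(interior_min, "interior_min")
  second_max <- check_count(second_max, "second_max")
  n <- check_count(n, "n")
  if (!(1L < first_max && first_max < interior_min &&
        interior_min < second_max && second_max <= n)) {
    abort_data("landmark indices must satisfy 1 < first_max < interior_min < second_max <= n")
  }
  structure(list(first_max = first_max, interior_min = interior_min,
                 second_max = second_max, n = n),
            class = "si_landmarks")
}

#' @export
print.si_landmarks <- function(x, ...) {
  cat(sprintf("<si_landmarks> first_max=%d interior_min=%d second_max=%d (n=%d)\n",
              x$first_max, x$interior_min, x$second_max, x$n))
  invisible(x)
}

# Centered moving average with window shrinking at the edges, so the output
# has the same length as the input and no boundary NA.
moving_average <- function(x, window) {
  if (window == 1L) return(x)
  half <- (window - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Detect the enhancement landmarks of an SI curve
#'
#' Locates, on a lightly smoothed copy of the curve, the first interior
#' local maximum that exceeds the initial SI, the global minimum after it
#' (the interior minimum), and the maximum of the remaining tail (the
#' second maximum; the final timepoint is eligible, since recovery may
#' still be rising when acquisition ends). Local maxima are non-strict and
#' ties are broken by the earliest index, which is robust to plateaus from
#' quantised SI. Indices are reported on the original axis; the ratio
#' statistics always read the unsmoothed values at those indices.
#'
#' @param curve An [si_curve()] of length >= 5.
#' @param smooth_window Odd moving-average window (samples) applied before
#'   the extremum search; 1 disables smoothing. Default 3.
#' @return An [si_landmarks()] object.
#' @section Failure modes: a monotone-decreasing curve, or one that never
#'   exceeds its initial SI, signals a `placentaq_no_first_maximum`
#'   condition; a curve whose minimum after the first maximum falls on the
#'   final timepoint has no recovery limb and signals
#'   `placentaq_no_recovery_limb`.
#' @examples
#' curve <- si_curve(c(1, 2, 3, 4, 5, 6) * 163, c(1, 2, 1, 0.5, 1.5, 2.5))
#' detect_landmarks(curve, smooth_window = 1)
#' @export
detect_landmarks <- function(curve, smooth_window = 3) {
  stopifnot(inherits(curve, "si_curve"))
  smooth_window <- check_count(smooth_window, "smooth_window")
  if (smooth_window %% 2L == 0L) {
    abort_config("`smooth_window` must be odd")
  }
  n <- length(curve$values)
  if (n < 5L) {
    abort_data("landmark detection needs at least 5 timepoints")
  }
  s <- moving_average(curve$values, smooth_window)
  interior <- 2:(n - 1L)
  is_max <- s[interior] >= s[interior - 1L] &
    s[interior] >= s[interior + 1L] &
    s[interior] > s[1L]
  if (!any(is_max)) {
    abort_no_first_maximum(sprintf(
      "curve %s has no interior local maximum above its initial SI", curve$id))
  }
  i1 <- interior[which(is_max)[1L]]
  imin <- i1 + which.min(s[(i1 + 1L):n])
  if (imin == n) {
    abort_no_recovery_limb(sprintf(
      "curve %s: SI minimum falls on the final timepoint; no recovery limb",
      curve$id))
  }
  i2 <- imin - 1L + which.max(s[imin:n])
  si_landmarks(i1, imin, i2, n)
}

#' SI initial enhancement
#'
#' The ratio between the SI at the first local maximum and the initial SI —
#' the first of the two landmark statistics of placental contrast dynamics.
#' The baseline is the first acquired timepoint (acquisition starts at
#' contrast administration, so there is no pre-injection frame).
#'
#' @param curve An [si_curve()].
#' @param landmarks An [si_landmarks()] for that curve (default: detected
#'   with [detect_landmarks()]).
#' @return Dimensionless ratio `SI[first_max] / SI[1]`, invariant under
#'   rescaling of the SI axis.
#' @export
initial_enhancement <- function(curve, landmarks = detect_landmarks(curve)) {
  stopifnot(inherits(curve, "si_curve"), inherits(landmarks, "si_landmarks"))
  if (landmarks$n != length(curve$values)) {
    abort_data("landmarks were computed for a curve of different length")
  }
  if (curve$values[1L] == 0) {
    abort_degenerate(sprintf("curve %s has zero initial SI", curve$id))
  }
  curve$values[landmarks$first_max] / curve$values[1L]
}

#' SI recovery
#'
#' The ratio between the SI at the second local maximum and the SI at the
#' minimum lying between the two maxima — the landmark statistic that
#' captures recycling of the contrast agent back into the maternal
#' circulation. On the smoothed series the ratio is >= 1 by construction;
#' on the unsmoothed values it may dip marginally below 1 and is reported
#' as computed.
#'
#' @inheritParams initial_enhancement
#' @return Dimensionless ratio `SI[second_max] / SI[interior_min]`.
#' @export
recovery <- function(curve, landmarks = detect_landmarks(curve)) {
  stopifnot(inherits(curve, "si_curve"), inherits(landmarks, "si_landmarks"))
  if (landmarks$n != length(curve$values)) {
    abort_data("landmarks were computed for a curve of different length")
  }
  vmin <- curve$values[landmarks$interior_min]
  if (vmin == 0) {
    abort_degenerate(sprintf("curve %s has zero SI at its interior minimum",
                             curve$id))
  }
  curve$values[landmarks$second_max] / vmin
}

#' Rate of enhancement scaled to the vena cava (ROE)
#'
#' The per-interval rate of SI change, scaled to the vena cava signal so
#' that curves from different animals are comparable:
#' `ROE_k = (SI_{k+1} - SI_k) / dt_min / C_vc`, in 1/min. The vena cava
#' reference `C_vc` is the mean of the first three timepoints after the
#' vena cava peak — its early plateau, the most stable single scalar
#' summary of the blood-pool signal.
#'
#' @param curve Placental [si_curve()].
#' @param vena_cava Vena cava [si_curve()] on the same schedule.
#' @return Numeric vector of length `length(curve) - 1` (units 1/min).
#' @examples
#' t <- (1:6) * 120
#' pl <- si_curve(t, seq(100, 200, length.out = 6))
#' vc <- si_curve(t, c(180, 200, 200, 200, 190, 185))
#' compute_roe(pl, vc)
#' @export
compute_roe <- function(curve, vena_cava) {
  stopifnot(inherits(curve, "si_curve"), inherits(vena_cava, "si_curve"))
  if (length(curve$times) != length(vena_cava$times) ||
      !isTRUE(all.equal(curve$times, vena_cava$times))) {
    abort_data("placental and vena cava curves are on different schedules")
  }
  n <- length(vena_cava$values)
  peak <- which.max(vena_cava$values)
  plateau <- seq.int(peak + 1L, length.out = 3L)
  plateau <- plateau[plateau <= n]
  if (length(plateau) == 0L) {
    abort_degenerate("vena cava peaks on the final timepoint; no post-peak plateau")
  }
  c_vc <- mean(vena_cava$values[plateau])
  if (c_vc <= 0) {
    abort_degenerate("vena cava reference level is not positive")
  }
  diff(curve$values) / (diff(curve$times) / 60) / c_vc
}

#' Landmark statistics for a whole cohort of curves
#'
#' Runs landmark detection and both ratio statistics on every curve. Curves
#' without a usable landmark structure (no first maximum, or no recovery
#' limb) are reported in a `failures` table with their reason — they are
#' never silently dropped — while the remaining curves populate the results.
#'
#' @param curves List of [si_curve()] objects (e.g. from
#'   [simulate_cohort()]).
#' @param smooth_window Passed to [detect_landmarks()].
#' @return A list of class `cohort_dynamics` with
#' \describe{
#'   \item{results}{data frame: `id`, `group`, `first_max_s`, `min_s`,
#'     `second_max_s` (landmark times in seconds), `initial_enhancement`,
#'     `recovery`.}
#'   \item{failures}{data frame: `id`, `group`, `reason`.}
#'   \item{summary}{per-group mean and SEM of both statistics.}
#' }
#' @export
analyze_cohort <- function(curves, smooth_window = 3) {
  if (length(curves) == 0L) {
    abort_data("`curves` is empty")
  }
  rows <- list()
  fails <- list()
  for (curve in curves) {
    res <- tryCatch({
      lm <- detect_landmarks(curve, smooth_window = smooth_window)
      data.frame(
        id = curve$id, group = curve$group,
        first_max_s = curve$times[lm$first_max],
        min_s = curve$times[lm$interior_min],
        second_max_s = curve$times[lm$second_max],
        initial_enhancement = initial_enhancement(curve, lm),
        recovery = recovery(curve, lm),
        stringsAsFactors = FALSE
      )
    }, placentaq_landmark_error = function(e) e,
       placentaq_degenerate_error = function(e) e)
    if (inherits(res, "condition")) {
      fails[[length(fails) + 1L]] <- data.frame(
        id = curve$id, group = curve$group,
        reason = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (length(rows) == 0L) {
    abort_pipeline("landmark analysis failed for every curve in the cohort")
  }
  results <- do.call(rbind, rows)
  failures <- if (length(fails)) {
    do.call(rbind, fails)
  } else {
    data.frame(id = character(0), group = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, lapply(split(results, results$group), function(d) {
    data.frame(group = d$group[1L], n = nrow(d),
               mean_initial_enhancement = mean(d$initial_enhancement),
               sem_initial_enhancement = sem(d$initial_enhancement),
               mean_recovery = mean(d$recovery),
               sem_recovery = sem(d$recovery),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  structure(list(results = results, failures = failures, summary = summary),
            class = "cohort_dynamics")
}

#' @export
print.cohort_dynamics <- function(x, ...) {
  cat(sprintf("<cohort_dynamics> %d curves analyzed, %d failures\n",
              nrow(x$results), nrow(x$failures)))
  print(x$summary, digits = 4)
  invisible(x)
}

sem <- function(x) {
  if (length(x) < 2L) return(0)
  stats::sd(x) / sqrt(length(x))
}
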