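#' Parameters of the biphasic placental enhancement curve
#'
#' The synthetic SI model reproduces the qualitative shape of the placental
#' enhancement curve after bolus injection of a macromolecular contrast
#' agent: a fast initial enhancement as the agent reaches (and is
#' internalised by) the labyrinth trophoblasts, a decline, and a late
#' recovery as the biotinylated agent is recycled back into the maternal
#' circulation. The noiseless curve is
#'
#' \deqn{S(t) = S_0 \left(1 + A_1 \, g(t; t_1) + A_2 \, h(t; t_0, r)\right)}
#'
#' with a gamma-variate uptake pulse \eqn{g(t; t_1) = (t/t_1) e^{1 - t/t_1}}
#' peaking at \eqn{t_1}, and a logistic recovery limb
#' \eqn{h(t; t_0, r) = 1 / (1 + e^{-r (t - t_0)})}. This family guarantees
#' exactly one early maximum followed by a late rise, which is the structure
#' the landmark definitions assume. Gaussian noise with standard deviation
#' `noise_sd` is added independently at each sampled timepoint.
#'
#' @param baseline Baseline signal `S0` (signal units, > 0).
#' @param uptake_amplitude Dimensionless uptake amplitude `A1` (>= 0).
#' @param uptake_time Time of the uptake peak `t1` in minutes (> 0).
#' @param recovery_amplitude Dimensionless recovery amplitude `A2` (>= 0).
#' @param recovery_onset Midpoint of the recovery rise, minutes.
#' @param recovery_rate Steepness of the recovery rise, 1/minutes (> 0).
#' @param noise_sd Standard deviation of additive Gaussian noise
#'   (signal units, >= 0).
#'
#' @return An object of class `curve_params`.
#' @examples
#' curve_params() # wild-type-like defaults
#' @export
curve_params <- function(baseline = 100,
                         uptake_amplitude = 0.6,
                         uptake_time = 8,
                         recovery_amplitude = 0.5,
                         recovery_onset = 45,
                         recovery_rate = 0.10,
                         noise_sd = 0) {
  check_number(baseline, "baseline", lower = 0, strict_lower = TRUE)
  check_number(uptake_amplitude, "uptake_amplitude", lower = 0)
  check_number(uptake_time, "uptake_time", lower = 0, strict_lower = TRUE)
  check_number(recovery_amplitude, "recovery_amplitude", lower = 0)
  check_number(recovery_onset, "recovery_onset", lower = 0, strict_lower = TRUE)
  check_number(recovery_rate, "recovery_rate", lower = 0, strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  structure(
    list(baseline = baseline,
         uptake_amplitude = uptake_amplitude,
         uptake_time = uptake_time,
         recovery_amplitude = recovery_amplitude,
         recovery_onset = recovery_onset,
         recovery_rate = recovery_rate,
         noise_sd = noise_sd),
    class = "curve_params"
  )
}

#' @export
print.curve_params <- function(x, ...) {
  cat(sprintf(
    "<curve_params> S0=%g A1=%g t1=%g min A2=%g onset=%g min rate=%g/min noise_sd=%g\n",
    x$baseline, x$uptake_amplitude, x$uptake_time, x$recovery_amplitude,
    x$recovery_onset, x$recovery_rate, x$noise_sd))
  invisible(x)
}

# Noiseless SI shape at time t (seconds).
si_shape <- function(t_seconds, params) {
  tm <- t_seconds / 60
  g <- (tm / params$uptake_time) * exp(1 - tm / params$uptake_time)
  h <- 1 / (1 + exp(-params$recovery_rate * (tm - params$recovery_onset)))
  params$baseline * (1 + params$uptake_amplitude * g +
                       params$recovery_amplitude * h)
}

#' Acquisition schedule of a dynamic MRI series
#'
#' Scans are back-to-back; the timepoint attributed to scan `k` (1-based) is
#' `k * scan_duration` (end-of-scan convention). With the default 25 scans of
#' 163 s each, the series ends at 4075 s = 67 min 55 s.
#'
#' @param n_scans Number of scans (>= 3).
#' @param scan_duration Duration of one scan in seconds (> 0).
#' @return An object of class `scan_schedule` with a `times` element
#'   (seconds).
#' @seealso [n_scans_in_window()]
#' @examples
#' scan_schedule() # 25 scans x 163 s
#' @export
scan_schedule <- function(n_scans = 25, scan_duration = 163) {
  n_scans <- check_count(n_scans, "n_scans", lower = 3L)
  check_number(scan_duration, "scan_duration", lower = 0, strict_lower = TRUE)
  structure(
    list(n_scans = n_scans, scan_duration = scan_duration,
         times = seq_len(n_scans) * scan_duration),
    class = "scan_schedule"
  )
}

#' @export
print.scan_schedule <- function(x, ...) {
  last <- x$times[x$n_scans]
  cat(sprintf("<scan_schedule> %d scans x %g s, ending at %d min %d s\n",
              x$n_scans, x$scan_duration, last %/% 60, round(last %% 60)))
  invisible(x)
}

#' Number of whole scans fitting in an acquisition window
#'
#' @param window_seconds Total acquisition window in seconds.
#' @param scan_duration Duration of one scan in seconds.
#' @return Integer count of complete scans.
#' @examples
#' n_scans_in_window(67 * 60 + 55, 2 * 60 + 43) # 25
#' @export
n_scans_in_window <- function(window_seconds, scan_duration) {
  check_number(window_seconds, "window_seconds", lower = 0, strict_lower = TRUE)
  check_number(scan_duration, "scan_duration", lower = 0, strict_lower = TRUE)
  as.integer(floor(window_seconds / scan_duration + 1e-9))
}

# Dense-grid evaluation of the noiseless ground truth. Landmarks are located
# on a grid oversampled `oversample`-fold relative to the scan schedule, so
# the truth is robust to later changes of the curve family.
curve_truth <- function(params, schedule, oversample = 1000) {
  grid <- seq(schedule$times[1L], schedule$times[schedule$n_scans],
              length.out = schedule$n_scans * oversample)
  v <- si_shape(grid, params)
  n <- length(v)
  interior <- 2:(n - 1L)
  is_max <- v[interior] >= v[interior - 1L] & v[interior] >= v[interior + 1L] &
    v[interior] > v[1L]
  if (!any(is_max)) {
    return(list(initial_enhancement = NA_real_, recovery = NA_real_,
                t_first_max = NA_real_, t_interior_min = NA_real_,
                t_second_max = NA_real_))
  }
  i1 <- interior[which(is_max)[1L]]
  imin <- i1 + which.min(v[(i1 + 1L):n])
  if (imin == n) {
    return(list(initial_enhancement = v[i1] / v[1L], recovery = NA_real_,
                t_first_max = grid[i1], t_interior_min = NA_real_,
                t_second_max = NA_real_))
  }
  i2 <- imin - 1L + which.max(v[imin:n])
  list(initial_enhancement = v[i1] / v[1L],
       recovery = v[i2] / v[imin],
       t_first_max = grid[i1],
       t_interior_min = grid[imin],
       t_second_max = grid[i2])
}

#' Simulate one placental SI curve
#'
#' Samples the biphasic curve model of [curve_params()] on a scan schedule
#' and adds Gaussian noise. The returned curve carries the ground-truth
#' landmark ratios of its noiseless shape, computed on a dense grid
#' (1000-fold oversampling), in its `truth` element — these are the values
#' a perfect landmark detector should recover.
#'
#' @param params A [curve_params()] object.
#' @param schedule A [scan_schedule()] object.
#' @param seed Integer seed; the same (params, schedule, seed) always
#'   produces an identical curve.
#' @param id,group Identifier and group label stored on the curve.
#' @return An [si_curve()] whose `truth` element lists
#'   `initial_enhancement`, `recovery` and the ground-truth landmark times
#'   (seconds).
#' @examples
#' curve <- simulate_si_curve(curve_params(noise_sd = 2), scan_schedule(),
#'                            seed = 1)
#' curve$truth$initial_enhancement
#' @export
simulate_si_curve <- function(params, schedule, seed, id = "sim",
                              group = NA_character_) {
  if (!inherits(params, "curve_params")) {
    abort_config("`params` must be a curve_params object")
  }
  if (!inherits(schedule, "scan_schedule")) {
    abort_config("`schedule` must be a scan_schedule object")
  }
  clean <- si_shape(schedule$times, params)
  noisy <- with_local_seed(seed, {
    clean + stats::rnorm(length(clean), mean = 0, sd = params$noise_sd)
  })
  noisy <- pmax(noisy, 0) # SI is non-negative by definition
  si_curve(times = schedule$times, values = noisy, id = id, group = group,
           truth = curve_truth(params, schedule))
}

#' Genotype presets for cohort simulation
#'
#' A preset bundles the curve parameters of one genotype with the
#' between-placenta variability of its amplitudes. The default table spans a
#' wild-type-like genotype, single knockouts of the senescence regulators
#' (Cdkn1a, p53, Cdkn2a), and the Cdkn2a;p53 double knockout, whose recovery
#' amplitude is the smallest of the panel (the planted effect is a graded
#' loss of the recovery limb, strongest when both regulatory arms are
#' disabled).
#'
#' @param name Genotype label.
#' @param params A [curve_params()] object.
#' @param between_placenta_sd Fractional standard deviation applied
#'   multiplicatively to both amplitudes across placentas (>= 0).
#' @return `genotype_preset()` returns a `genotype_preset` object;
#'   `genotype_presets()` returns the default named list of presets.
#' @examples
#' presets <- genotype_presets()
#' names(presets)
#' @export
genotype_preset <- function(name, params, between_placenta_sd = 0.1) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort_config("`name` must be a non-empty string")
  }
  if (!inherits(params, "curve_params")) {
    abort_config("`params` must be a curve_params object")
  }
  check_number(between_placenta_sd, "between_placenta_sd", lower = 0)
  structure(
    list(name = name, params = params,
         between_placenta_sd = between_placenta_sd),
    class = "genotype_preset"
  )
}

#' @rdname genotype_preset
#' @param noise_sd Measurement noise applied to every preset (signal units).
#' @param between_placenta_sd Shared fractional amplitude variability.
#' @export
genotype_presets <- function(noise_sd = 2, between_placenta_sd = 0.1) {
  base <- function(A1, A2) {
    curve_params(baseline = 100, uptake_amplitude = A1, uptake_time = 8,
                 recovery_amplitude = A2, recovery_onset = 45,
                 recovery_rate = 0.10, noise_sd = noise_sd)
  }
  presets <- list(
    genotype_preset("WT", base(0.60, 0.50), between_placenta_sd),
    genotype_preset("Cdkn1a_KO", base(0.60, 0.45), between_placenta_sd),
    genotype_preset("p53_KO", base(0.60, 0.30), between_placenta_sd),
    genotype_preset("Cdkn2a_KO", base(0.60, 0.30), between_placenta_sd),
    genotype_preset("Cdkn2a_p53_DKO", base(0.40, 0.10), between_placenta_sd)
  )
  names(presets) <- vapply(presets, `[[`, character(1), "name")
  validate_preset_table(presets)
  presets
}

validate_preset_table <- function(presets) {
  if (length(presets) == 0L) {
    abort_config("preset table is empty")
  }
  nm <- vapply(presets, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    abort_config(sprintf("duplicated preset name: %s", nm[duplicated(nm)][1L]))
  }
  a2 <- vapply(presets, function(p) p$params$recovery_amplitude, numeric(1))
  dko <- grepl("DKO", nm)
  if (any(dko) && a2[which(dko)[1L]] > min(a2)) {
    abort_config("the double-knockout preset must have the smallest recovery amplitude")
  }
  invisible(presets)
}

#' Simulate a multi-genotype cohort of SI curves
#'
#' Generates `n_per_group` placentas per genotype preset. For each placenta
#' the two amplitudes are jittered multiplicatively by a Gaussian factor with
#' the preset's `between_placenta_sd` (truncated at zero), then a curve is
#' sampled with the preset's measurement noise. Each curve carries the
#' ground truth of its own jittered noiseless shape. Sub-seeds are derived
#' deterministically per placenta, so the cohort is reproducible and
#' insensitive to preset order.
#'
#' @param presets Named list of [genotype_preset()] objects.
#' @param n_per_group Placentas per genotype (>= 1).
#' @param schedule A [scan_schedule()].
#' @param seed Integer seed.
#' @return A list of [si_curve()] objects (class `si_cohort`), ids
#'   `<genotype>_<k>`, each with its ground-truth `truth` element.
#' @examples
#' cohort <- simulate_cohort(genotype_presets(), n_per_group = 3,
#'                           schedule = scan_schedule(), seed = 7)
#' length(cohort)
#' @export
simulate_cohort <- function(presets, n_per_group, schedule, seed) {
  validate_preset_table(presets)
  n_per_group <- check_count(n_per_group, "n_per_group", lower = 1L)
  curves <- vector("list", length(presets) * n_per_group)
  k <- 0L
  for (gi in seq_along(presets)) {
    preset <- presets[[gi]]
    for (j in seq_len(n_per_group)) {
      k <- k + 1L
      s <- sub_seed(seed, (gi - 1L) * 100000L + j)
      jit <- with_local_seed(s, {
        pmax(1 + stats::rnorm(2, 0, preset$between_placenta_sd), 0)
      })
      p <- preset$params
      p$uptake_amplitude <- p$uptake_amplitude * jit[1L]
      p$recovery_amplitude <- p$recovery_amplitude * jit[2L]
      curves[[k]] <- simulate_si_curve(
        p, schedule, seed = sub_seed(s, 1L),
        id = sprintf("%s_%d", preset$name, j), group = preset$name
      )
    }
  }
  structure(curves, class = c("si_cohort", "list"))
}

#' @export
print.si_cohort <- function(x, ...) {
  groups <- table(vapply(x, `[[`, character(1), "group"))
  cat(sprintf("<si_cohort> %d curves: %s\n", length(x),
              paste(sprintf("%s (n=%d)", names(groups), groups),
                    collapse = ", ")))
  invisible(x)
}
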