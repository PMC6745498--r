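# Independent oracles used across the suite. These re-derive expected values
# by brute force (explicit loops, closed-form formulas) and deliberately do
# not call the package code paths they check.

# Noiseless curve value at time t (seconds) -- re-coded from the model
# definition, not via si_shape().
oracle_curve_value <- function(t_seconds, baseline, A1, t1_min, A2,
                               onset_min, rate_per_min) {
  tm <- t_seconds / 60
  uptake <- (tm / t1_min) * exp(1 - tm / t1_min)
  recovery <- 1 / (1 + exp(-rate_per_min * (tm - onset_min)))
  baseline * (1 + A1 * uptake + A2 * recovery)
}

# Dense-grid brute-force landmark oracle: evaluates the noiseless curve on a
# fine grid and walks it with plain loops.
oracle_landmark_truth <- function(params, schedule, n_dense = 60000) {
  grid <- seq(schedule$times[1L], schedule$times[schedule$n_scans],
              length.out = n_dense)
  v <- oracle_curve_value(grid, params$baseline, params$uptake_amplitude,
                          params$uptake_time, params$recovery_amplitude,
                          params$recovery_onset, params$recovery_rate)
  n <- length(v)
  i1 <- NA_integer_
  for (i in 2:(n - 1L)) {
    if (v[i] >= v[i - 1L] && v[i] >= v[i + 1L] && v[i] > v[1L]) {
      i1 <- i
      break
    }
  }
  if (is.na(i1)) return(NULL)
  imin <- i1 + 1L
  for (i in (i1 + 1L):n) if (v[i] < v[imin]) imin <- i
  if (imin == n) return(NULL)
  i2 <- imin
  for (i in imin:n) if (v[i] > v[i2]) i2 <- i
  list(E = v[i1] / v[1L], R = v[i2] / v[imin],
       t_first_max = grid[i1], t_interior_min = grid[imin],
       t_second_max = grid[i2])
}

# Brute-force counting oracles -----------------------------------------

oracle_percent_positive <- function(syncytia) {
  n_pos <- 0L
  for (s in syncytia) if (sum(s) >= 1L) n_pos <- n_pos + 1L
  100 * n_pos / length(syncytia)
}

oracle_fusion_nuclei <- function(counts) {
  fused_nuclei <- 0L
  for (k in counts) if (k >= 2L) fused_nuclei <- fused_nuclei + k
  100 * fused_nuclei / sum(counts)
}

oracle_fusion_cells <- function(counts) {
  fused <- 0L
  for (k in counts) if (k >= 2L) fused <- fused + 1L
  100 * fused / length(counts)
}

# Rubric lookup oracle: explicit edge table scanned linearly.
oracle_ki67 <- function(f) {
  if (f == 0) return(0)
  edges <- c(0.05, 0.10, 0.25, 0.33, 0.50, 0.66, 0.75)
  scores <- c(0.5, 1, 1.5, 2, 2.5, 3, 3.5)
  for (b in seq_along(edges)) {
    if (f < edges[b]) return(scores[b])
  }
  if (f == 0.75) return(3.5)
  4
}

# Classical pooled-variance t statistic and two-sided p from first
# principles.
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  tval <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = tval, df = na + nb - 2,
       p = 2 * stats::pt(-abs(tval), na + nb - 2))
}

# One-way ANOVA F/p and Tukey adjusted p from sums of squares.
oracle_anova <- function(values, groups) {
  g <- factor(groups)
  k <- nlevels(g)
  n <- length(values)
  grand <- mean(values)
  means <- tapply(values, g, mean)
  ns <- tapply(values, g, length)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((values - means[g])^2)
  mse <- ssw / (n - k)
  Fval <- (ssb / (k - 1)) / mse
  pairs <- utils::combn(levels(g), 2L)
  tukey_p <- apply(pairs, 2L, function(pr) {
    se <- sqrt(mse / 2 * (1 / ns[pr[1L]] + 1 / ns[pr[2L]]))
    q <- abs(means[pr[2L]] - means[pr[1L]]) / se
    stats::ptukey(q, k, n - k, lower.tail = FALSE)
  })
  names(tukey_p) <- sprintf("%s-%s", pairs[2L, ], pairs[1L, ])
  list(F = Fval, p = stats::pf(Fval, k - 1, n - k, lower.tail = FALSE),
       tukey_p = tukey_p)
}

# Per-voxel summation mean oracle for ROI extraction.
oracle_roi_mean <- function(volume, mask) {
  tot <- 0
  cnt <- 0L
  idx <- which(as.logical(mask))
  for (i in idx) {
    tot <- tot + volume[i]
    cnt <- cnt + 1L
  }
  tot / cnt
}

# Finite-difference ROE oracle.
oracle_roe <- function(si, times_s, c_vc) {
  out <- numeric(length(si) - 1L)
  for (k in seq_len(length(si) - 1L)) {
    out[k] <- (si[k + 1L] - si[k]) / ((times_s[k + 1L] - times_s[k]) / 60) / c_vc
  }
  out
}

# The parameter sweep used for oracle-equivalence checks: spans the
# amplitude range of the genotype panel (with jitter headroom) and realistic
# variation of the recovery limb and baseline at the panel's uptake time.
preset_sweep <- function() {
  expand.grid(A1 = c(0.4, 0.5, 0.6), A2 = c(0.08, 0.1, 0.3, 0.45, 0.55),
              onset = c(42, 45, 48), rate = c(0.09, 0.10, 0.12),
              S0 = c(80, 120))
}

sweep_params <- function(row) {
  curve_params(baseline = row$S0, uptake_amplitude = row$A1,
               uptake_time = 8, recovery_amplitude = row$A2,
               recovery_onset = row$onset, recovery_rate = row$rate,
               noise_sd = 0)
}

random_valid_curve <- function(n = 12) {
  # random curve guaranteed to have the two-maxima structure
  v <- c(1, 2 + stats::runif(1), sort(stats::runif(floor((n - 4) / 2)),
                                      decreasing = TRUE) * 0.8 + 0.5,
         0.3, sort(stats::runif(n - 4 - floor((n - 4) / 2))) * 2 + 0.5,
         3 + stats::runif(1))
  si_curve(seq_along(v) * 60, v)
}
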