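test_that("ROI extraction reproduces single-voxel trajectories and uniform volumes", {
  times <- (1:4) * 163
  vol <- array(0, dim = c(3, 3, 2, 4))
  traj <- c(5, 9, 2, 7)
  for (k in 1:4) vol[2, 2, 1, k] <- traj[k]
  mask <- array(FALSE, dim = c(3, 3, 2))
  mask[2, 2, 1] <- TRUE
  cu <- extract_roi_timeseries(vol, mask, times)
  expect_equal(cu$values, traj)

  uni <- array(rep(c(10, 20, 30, 40), each = 18), dim = c(3, 3, 2, 4))
  cu2 <- extract_roi_timeseries(uni, array(TRUE, dim = c(3, 3, 2)), times)
  expect_equal(cu2$values, c(10, 20, 30, 40))
})

test_that("ROI means equal a brute-force per-voxel summation oracle", {
  set.seed(31)
  for (rep in 1:50) {
    dims <- c(sample(2:5, 1), sample(2:5, 1), sample(1:3, 1))
    n_t <- sample(3:6, 1)
    vol <- array(runif(prod(dims) * n_t, 0, 100), dim = c(dims, n_t))
    masks <- lapply(seq_len(n_t), function(k) {
      m <- array(runif(prod(dims)) < 0.5, dim = dims)
      if (!any(m)) m[1] <- TRUE
      m
    })
    cu <- extract_roi_timeseries(vol, masks, times = (1:n_t) * 100)
    expected <- vapply(seq_len(n_t), function(k) {
      idx <- slice.index(vol, length(dims) + 1L) == k
      oracle_roi_mean(array(vol[idx], dim = dims), masks[[k]])
    }, numeric(1))
    expect_equal(cu$values, expected, tolerance = 1e-12)
  }
})

test_that("empty masks and shape mismatches are data errors naming the problem", {
  vol <- array(1, dim = c(2, 2, 1, 3))
  empty <- array(FALSE, dim = c(2, 2, 1))
  full <- array(TRUE, dim = c(2, 2, 1))
  expect_error(extract_roi_timeseries(vol, list(full, empty, full), (1:3) * 10),
               "timepoint 2", class = "placentaq_data_error")
  expect_error(extract_roi_timeseries(vol, array(TRUE, dim = c(3, 2, 1)),
                                      (1:3) * 10),
               class = "placentaq_data_error")
})

test_that("landmark detection matches the worked-out toy curve", {
  cu <- si_curve((1:6) * 163, c(1, 2, 1, 0.5, 1.5, 2.5))
  lm <- detect_landmarks(cu, smooth_window = 1)
  expect_equal(lm$first_max, 2L)
  expect_equal(lm$interior_min, 4L)
  expect_equal(lm$second_max, 6L)
  expect_equal(initial_enhancement(cu, lm), 2)
  expect_equal(recovery(cu, lm), 5)
})

test_that("curves without the biphasic structure raise classed landmark errors", {
  falling <- si_curve((1:8) * 60, seq(8, 1))
  expect_error(detect_landmarks(falling),
               class = "placentaq_no_first_maximum")
  # single peak then monotone decline to the end: no recovery limb
  mono <- si_curve((1:8) * 60, c(1, 3, 5, 4, 3, 2, 1.5, 1))
  expect_error(detect_landmarks(mono, smooth_window = 1),
               class = "placentaq_no_recovery_limb")
  short <- si_curve((1:4) * 60, c(1, 2, 1, 2))
  expect_error(detect_landmarks(short), class = "placentaq_data_error")
})

test_that("noiseless sweep landmarks agree with the dense-grid oracle", {
  sched <- scan_schedule()
  sweep <- preset_sweep()
  expect_gte(nrow(sweep), 200)
  for (i in seq_len(nrow(sweep))) {
    p <- sweep_params(sweep[i, ])
    cu <- simulate_si_curve(p, sched, seed = 1)
    lm <- detect_landmarks(cu)
    oracle <- oracle_landmark_truth(p, sched)
    expect_false(is.null(oracle))
    expect_lte(abs(cu$times[lm$first_max] - oracle$t_first_max),
               sched$scan_duration)
    expect_lte(abs(cu$times[lm$interior_min] - oracle$t_interior_min),
               sched$scan_duration)
    expect_lte(abs(cu$times[lm$second_max] - oracle$t_second_max),
               sched$scan_duration)
    expect_lt(abs(initial_enhancement(cu, lm) / oracle$E - 1), 0.02)
    expect_lt(abs(recovery(cu, lm) / oracle$R - 1), 0.02)
  }
})

test_that("E and R are scale invariant and recovery ordering follows the planted amplitude", {
  sched <- scan_schedule()
  base <- simulate_si_curve(curve_params(noise_sd = 1.5), sched, seed = 8)
  lm <- detect_landmarks(base)
  for (c_scale in c(0.1, 3, 1000)) {
    scaled <- si_curve(base$times, base$values * c_scale)
    lms <- detect_landmarks(scaled)
    expect_identical(unclass(lms), unclass(lm))
    expect_equal(initial_enhancement(scaled, lms),
                 initial_enhancement(base, lm), tolerance = 1e-12)
    expect_equal(recovery(scaled, lms), recovery(base, lm),
                 tolerance = 1e-12)
  }
  # monotone ordering in A2 on noiseless curves
  r <- vapply(c(0.1, 0.2, 0.35, 0.5), function(a2) {
    cu <- simulate_si_curve(curve_params(recovery_amplitude = a2,
                                         noise_sd = 0), sched, seed = 1)
    recovery(cu, detect_landmarks(cu))
  }, numeric(1))
  expect_true(all(diff(r) >= 0))
})

test_that("time-unit reparameterization leaves E and R unchanged and rescales ROE", {
  sched <- scan_schedule()
  cu <- simulate_si_curve(curve_params(noise_sd = 1), sched, seed = 4)
  halved <- si_curve(cu$times / 2, cu$values)
  lm1 <- detect_landmarks(cu)
  lm2 <- detect_landmarks(halved)
  expect_equal(initial_enhancement(halved, lm2), initial_enhancement(cu, lm1))
  expect_equal(recovery(halved, lm2), recovery(cu, lm1))
  vc <- si_curve(cu$times, rep(c(150, 200, 200, 200), length.out = 25))
  vch <- si_curve(halved$times, vc$values)
  expect_equal(compute_roe(halved, vch), 2 * compute_roe(cu, vc))
})

test_that("ROE matches its definition on linear and constant curves and a random oracle", {
  # linear rise 100 -> 200 over 10 min scaled to C_vc = 200: 0.05 / min
  times <- seq(0, 600, by = 120)[-1] # 5 points, 2-min spacing
  pl <- si_curve(times, seq(120, 200, length.out = 5))
  vc <- si_curve(times, c(100, 200, 200, 200, 200))
  roe <- compute_roe(pl, vc)
  expect_equal(roe, rep(0.05, 4), tolerance = 1e-12)
  const <- si_curve(times, rep(140, 5))
  expect_equal(compute_roe(const, vc), rep(0, 4))
  set.seed(17)
  for (rep in 1:20) {
    v <- runif(8, 50, 150)
    p2 <- si_curve((1:8) * 97, v)
    vcv <- c(runif(1, 100, 120), 200, runif(6, 150, 190))
    vc2 <- si_curve((1:8) * 97, vcv)
    c_vc <- mean(vcv[3:5]) # peak at index 2: plateau = next three
    expect_equal(compute_roe(p2, vc2), oracle_roe(v, (1:8) * 97, c_vc),
                 tolerance = 1e-12)
  }
})

test_that("cohort analysis keeps failures first-class and computes group SEM", {
  sched <- scan_schedule()
  ok <- simulate_si_curve(curve_params(noise_sd = 0), sched, seed = 1,
                          id = "ok1", group = "WT")
  res <- analyze_cohort(list(ok, ok, ok))
  expect_equal(res$summary$sem_initial_enhancement, 0)
  expect_equal(res$summary$sem_recovery, 0)

  bad <- si_curve(sched$times, seq(200, 10, length.out = 25), id = "bad",
                  group = "WT")
  mixed <- analyze_cohort(list(ok, ok, bad))
  expect_equal(nrow(mixed$results), 2)
  expect_equal(mixed$failures$id, "bad")
  expect_match(mixed$failures$reason, "maximum")

  expect_error(analyze_cohort(list(bad)), class = "placentaq_pipeline_error")
})
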