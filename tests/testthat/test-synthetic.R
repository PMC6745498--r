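test_that("zero amplitudes give a flat noiseless curve at baseline", {
  p <- curve_params(baseline = 100, uptake_amplitude = 0,
                    recovery_amplitude = 0, noise_sd = 0)
  cu <- simulate_si_curve(p, scan_schedule(), seed = 1)
  expect_equal(cu$values, rep(100, 25))
})

test_that("curve simulation is deterministic under the seed", {
  p <- curve_params(noise_sd = 3)
  a <- simulate_si_curve(p, scan_schedule(), seed = 42)
  b <- simulate_si_curve(p, scan_schedule(), seed = 42)
  expect_identical(a$values, b$values)
  c <- simulate_si_curve(p, scan_schedule(), seed = 43)
  expect_false(identical(a$values, c$values))
})

test_that("generators do not disturb the caller's random stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(simulate_si_curve(curve_params(noise_sd = 1), scan_schedule(),
                              seed = 7))
  expect_identical(runif(1), before)
})

test_that("spec'd WT-like ground truth matches the dense-grid brute-force oracle", {
  # explicit parameter choice exercising an early-onset recovery limb
  p <- curve_params(baseline = 100, uptake_amplitude = 0.6, uptake_time = 8,
                    recovery_amplitude = 0.5, recovery_onset = 30,
                    recovery_rate = 0.25, noise_sd = 0)
  cu <- simulate_si_curve(p, scan_schedule(), seed = 1)
  oracle <- oracle_landmark_truth(p, scan_schedule())
  expect_equal(cu$truth$initial_enhancement, oracle$E, tolerance = 1e-3)
  expect_equal(cu$truth$recovery, oracle$R, tolerance = 1e-3)
})

test_that("ground-truth recovery is non-decreasing in the recovery amplitude", {
  sched <- scan_schedule()
  a2 <- seq(0.1, 0.7, by = 0.1)
  r <- vapply(a2, function(x) {
    p <- curve_params(recovery_amplitude = x, noise_sd = 0)
    simulate_si_curve(p, sched, seed = 1)$truth$recovery
  }, numeric(1))
  expect_true(all(diff(r) >= 0))
})

test_that("cohort has the requested size and labels, and is degenerate-variance exact", {
  presets <- genotype_presets(noise_sd = 0, between_placenta_sd = 0)[c("WT", "Cdkn2a_p53_DKO")]
  coh <- simulate_cohort(presets, 3, scan_schedule(), seed = 5)
  expect_length(coh, 6)
  groups <- vapply(coh, `[[`, character(1), "group")
  expect_equal(as.vector(table(groups)[c("WT", "Cdkn2a_p53_DKO")]), c(3L, 3L))
  # no noise, no jitter: within-group curves identical
  wt <- coh[groups == "WT"]
  expect_identical(wt[[1]]$values, wt[[2]]$values)
  expect_identical(wt[[2]]$values, wt[[3]]$values)
})

test_that("group mean ground-truth recovery is larger for WT than DKO", {
  presets <- genotype_presets(noise_sd = 0, between_placenta_sd = 0.05)
  coh <- simulate_cohort(presets[c("WT", "Cdkn2a_p53_DKO")], 8,
                         scan_schedule(), seed = 11)
  groups <- vapply(coh, `[[`, character(1), "group")
  truth_r <- vapply(coh, function(cu) cu$truth$recovery, numeric(1))
  expect_gt(mean(truth_r[groups == "WT"]),
            mean(truth_r[groups == "Cdkn2a_p53_DKO"]))
})

test_that("empty preset list and invalid schedules are configuration errors", {
  expect_error(simulate_cohort(list(), 3, scan_schedule(), seed = 1),
               class = "placentaq_config_error")
  expect_error(scan_schedule(n_scans = 2), class = "placentaq_config_error")
})

test_that("syncytia fields honour p = 0 and p = 1 exactly and conserve counts", {
  f0 <- simulate_syncytia_fields(5, 8, c(2, 6), p_nucleus_positive = 0,
                                 seed = 2)
  expect_true(all(vapply(f0, percent_positive_syncytia, numeric(1)) == 0))
  f1 <- simulate_syncytia_fields(5, 8, c(2, 6), p_nucleus_positive = 1,
                                 seed = 2)
  expect_true(all(vapply(f1, percent_positive_syncytia, numeric(1)) == 100))
  for (f in f1) {
    expect_length(f$syncytia, 8)
    expect_true(all(lengths(f$syncytia) >= 2 & lengths(f$syncytia) <= 6))
  }
})

test_that("binomial positivity rate is recovered at large n", {
  fields <- simulate_syncytia_fields(10, 1000, 1, p_nucleus_positive = 0.1,
                                     seed = 7)
  frac <- mean(vapply(fields, percent_positive_syncytia, numeric(1))) / 100
  se <- sqrt(0.1 * 0.9 / 10000)
  expect_lt(abs(frac - 0.1), 3 * se)
})

test_that("intensity image plants the exact pre-noise positive fraction", {
  img <- simulate_intensity_image(c(40, 50), 0.5, noise_sd = 0, seed = 3)
  expect_equal(attr(img, "truth")$positive_fraction, 0.5)
  expect_equal(mean(img$pixels > 0.5), 0.5)
  img0 <- simulate_intensity_image(c(10, 10), 0, noise_sd = 0, seed = 3)
  expect_true(all(img0$pixels == 0.2))
  expect_error(simulate_intensity_image(c(10, 10), 0.5, fg_level = 0.2,
                                        bg_level = 0.4, seed = 1),
               class = "placentaq_config_error")
})

test_that("noiseless planted expression folds are exact", {
  em <- simulate_expression_matrix(100, 4, planted_up = list(genes = 1, fold = 2),
                                   noise_sd_log2 = 0, seed = 1)
  v <- em$values
  expect_equal(mean(v[1, em$groups == "late"]) / mean(v[1, em$groups == "early"]),
               2, tolerance = 1e-12)
  # non-planted gene: equal group means
  expect_equal(mean(v[2, em$groups == "late"]),
               mean(v[2, em$groups == "early"]), tolerance = 1e-12)
})

test_that("overlapping planted sets are rejected", {
  expect_error(
    simulate_expression_matrix(100, 3,
                               planted_up = list(genes = 1:10, fold = 2),
                               planted_down = list(genes = 5:12, fold = 2),
                               seed = 1),
    class = "placentaq_config_error")
})
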