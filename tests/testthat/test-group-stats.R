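test_that("identical groups give t = 0, p = 1 and one-tailed p halves the two-tailed p", {
  res <- t_test(c(3, 3, 3), c(3, 3, 3))
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_false(res$degenerate)

  a <- c(5.1, 6.2, 7.3, 5.9)
  b <- c(3.0, 3.5, 4.1, 2.8)
  two <- t_test(a, b, tails = 2)
  one <- t_test(a, b, tails = 1, direction = "greater")
  expect_equal(one$p, two$p / 2, tolerance = 1e-12)
  expect_equal(one$direction, "A>B")
})

test_that("constant groups with unequal means are flagged as degenerate", {
  res <- t_test(c(2, 2), c(5, 5))
  expect_true(res$degenerate)
  expect_equal(res$p, 0)
})

test_that("pooled t statistics match the first-principles formula on random pairs", {
  set.seed(41)
  for (rep in 1:100) {
    a <- rnorm(sample(3:10, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 2))
    b <- rnorm(sample(3:10, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 2))
    got <- t_test(a, b)
    exp <- oracle_pooled_t(a, b)
    expect_equal(got$t, exp$t, tolerance = 1e-10)
    expect_equal(got$p, exp$p, tolerance = 1e-10)
    expect_equal(got$df, exp$df)
  }
})

test_that("flat data returns the F = 0, p = 1 convention with unit Tukey p", {
  at <- anova_tukey(group_table(rep(4, 9), rep(c("a", "b", "c"), each = 3)))
  expect_equal(at$F, 0)
  expect_equal(at$p, 1)
  expect_true(all(at$tukey$p_adjusted == 1))
})

test_that("two-group ANOVA satisfies F = t squared", {
  set.seed(13)
  for (rep in 1:20) {
    a <- rnorm(5); b <- rnorm(6, 1)
    at <- anova_tukey(group_table(c(a, b), rep(c("A", "B"), c(5, 6))))
    tt <- t_test(a, b)
    expect_equal(at$F, tt$t^2, tolerance = 1e-10)
  }
})

test_that("ANOVA and Tukey agree with the sums-of-squares oracle on random tables", {
  set.seed(29)
  for (rep in 1:100) {
    k <- sample(3:5, 1)
    ns <- sample(3:7, k, replace = TRUE)
    values <- unlist(lapply(seq_len(k), function(g) {
      rnorm(ns[g], mean = runif(1, 0, 3))
    }))
    groups <- rep(sprintf("g%02d", seq_len(k)), ns)
    got <- anova_tukey(group_table(values, groups))
    exp <- oracle_anova(values, groups)
    expect_equal(got$F, exp$F, tolerance = 1e-8)
    expect_equal(got$p, exp$p, tolerance = 1e-8)
    expect_equal(got$tukey$p_adjusted,
                 unname(exp$tukey_p[got$tukey$comparison]), tolerance = 1e-8)
    # family-wise contract and p-value ranges
    expect_true(all(got$tukey$p_adjusted >= got$tukey$p_unadjusted - 1e-12))
    expect_true(all(got$tukey$p_adjusted >= 0 & got$tukey$p_adjusted <= 1))
  }
})

test_that("groups with a single observation are rejected for variance-based tests", {
  expect_error(anova_tukey(group_table(c(1, 2, 3), c("a", "a", "b"))),
               class = "placentaq_data_error")
  expect_error(t_test(1, c(2, 3)), class = "placentaq_data_error")
})

test_that("fold-change filter is boundary inclusive and sorts by effect size", {
  m <- rbind(g_at = c(10, 10, 18, 18),    # exactly 1.8-fold up
             g_eq = c(10, 10, 10, 10),    # unchanged
             g_dn = c(10, 10, 2, 2),      # 5-fold down
             g_up = c(10, 10, 40, 40))    # 4-fold up
  rownames(m) <- c("g_at", "g_eq", "g_dn", "g_up")
  colnames(m) <- paste0("s", 1:4)
  em <- expression_matrix(m, c("early", "early", "late", "late"))
  res <- fold_change_filter(em, threshold = 1.8)
  expect_equal(res$n_selected, 3)
  expect_equal(res$selected$gene, c("g_dn", "g_up", "g_at"))
  expect_equal(res$selected$direction, c("down", "up", "up"))
})

test_that("swapping group labels maps selected fold changes to reciprocals", {
  em <- simulate_expression_matrix(300, 4,
                                   planted_up = list(n = 10, fold = 2.5),
                                   planted_down = list(genes = 291:300,
                                                       fold = 3),
                                   noise_sd_log2 = 0.05, seed = 6)
  res <- fold_change_filter(em)
  flipped <- expression_matrix(em$values,
                               ifelse(em$groups == "early", "late", "early"))
  res2 <- fold_change_filter(flipped)
  expect_setequal(res$selected$gene, res2$selected$gene)
  fc1 <- res$selected$fc[order(res$selected$gene)]
  fc2 <- res2$selected$fc[order(res2$selected$gene)]
  expect_equal(fc1, 1 / fc2, tolerance = 1e-12)
})

test_that("genes with zero early mean are excluded and reported", {
  m <- rbind(gz = c(0, 0, 5, 5), gk = c(10, 10, 30, 30))
  colnames(m) <- paste0("s", 1:4)
  em <- expression_matrix(m, c("early", "early", "late", "late"))
  res <- fold_change_filter(em)
  expect_equal(res$excluded$gene, "gz")
  expect_equal(res$selected$gene, "gk")
})

test_that("noiseless planted matrices are recovered exactly by the filter", {
  em <- simulate_expression_matrix(500, 4,
                                   planted_up = list(n = 12, fold = 2),
                                   noise_sd_log2 = 0, seed = 2)
  res <- fold_change_filter(em, threshold = 1.8)
  expect_setequal(res$selected$gene, attr(em, "truth")$up)
  none <- simulate_expression_matrix(200, 4, noise_sd_log2 = 0, seed = 2)
  expect_equal(fold_change_filter(none)$n_selected, 0)
})

test_that("group summaries return mean and SEM with singleton flags", {
  s <- summarize_groups(group_table(c(2, 4, 6, 9), c("a", "a", "a", "b")))
  a_row <- s[s$group == "a", ]
  expect_equal(a_row$mean, 4)
  expect_equal(a_row$sem, sd(c(2, 4, 6)) / sqrt(3))
  expect_equal(a_row$sem, 1.1547, tolerance = 1e-4)
  b_row <- s[s$group == "b", ]
  expect_false(b_row$sem_defined)
  expect_equal(b_row$sem, 0)
})
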