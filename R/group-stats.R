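#' Measurements grouped by experimental condition
#'
#' A light validated container for one measurement per experimental unit
#' (placenta, field of view, culture) with a group label, the structure all
#' group comparisons operate on.
#'
#' @param values Numeric measurements.
#' @param groups Group label per measurement.
#' @param unit_id Optional unit identifiers.
#' @param label Name of the measurement.
#' @return A data frame of class `group_table` with columns `unit_id`,
#'   `group`, `value`.
#' @export
group_table <- function(values, groups, unit_id = NULL,
                        label = "measurement") {
  if (!is.numeric(values) || length(values) == 0L || anyNA(values)) {
    abort_data("`values` must be a non-empty numeric vector without NAs")
  }
  groups <- as.character(groups)
  if (length(groups) != length(values) || anyNA(groups)) {
    abort_data("`groups` must label every value")
  }
  if (is.null(unit_id)) unit_id <- sprintf("u%d", seq_along(values))
  out <- data.frame(unit_id = as.character(unit_id), group = groups,
                    value = values, stringsAsFactors = FALSE)
  attr(out, "label") <- label
  class(out) <- c("group_table", "data.frame")
  out
}

#' Unpaired Student's t-test between two groups
#'
#' Classical pooled-variance (Student) unpaired t-test, the package default
#' because that is the test named throughout the comparisons this toolkit
#' reproduces; Welch's unequal-variance variant is available behind a flag.
#' For a one-tailed test the alternative states the hypothesised direction
#' and the p-value is half the two-tailed p when the observed effect lies in
#' that direction.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param tails 1 or 2 (default 2).
#' @param direction Hypothesised direction for `tails = 1`: `"greater"`
#'   (mean A > mean B, default) or `"less"`.
#' @param welch Use Welch's unequal-variance test instead of pooled.
#' @return List with `t`, `df`, `p`, `direction` (observed: `"A>B"`,
#'   `"A<B"` or `"equal"`) and `degenerate` (TRUE when both groups are
#'   constant with unequal means, where significance is formally infinite).
#'   Two constant groups with equal means return `t = 0`, `p = 1`.
#' @examples
#' t_test(c(5, 6, 7), c(1, 2, 3))
#' @export
t_test <- function(group_a, group_b, tails = 2,
                   direction = c("greater", "less"), welch = FALSE) {
  direction <- match.arg(direction)
  if (!tails %in% c(1, 2)) abort_config("`tails` must be 1 or 2")
  if (length(group_a) < 2L || length(group_b) < 2L) {
    abort_data("each group needs at least 2 observations")
  }
  if (anyNA(group_a) || anyNA(group_b)) {
    abort_data("groups must not contain missing values")
  }
  da <- mean(group_a) - mean(group_b)
  observed <- if (da > 0) "A>B" else if (da < 0) "A<B" else "equal"
  pooled_var <- (sum((group_a - mean(group_a))^2) +
                 sum((group_b - mean(group_b))^2)) /
    (length(group_a) + length(group_b) - 2L)
  if (pooled_var == 0) {
    if (da == 0) {
      return(list(t = 0, df = length(group_a) + length(group_b) - 2L,
                  p = 1, direction = "equal", degenerate = FALSE))
    }
    return(list(t = sign(da) * Inf,
                df = length(group_a) + length(group_b) - 2L,
                p = 0, direction = observed, degenerate = TRUE))
  }
  alternative <- if (tails == 2) "two.sided" else direction
  fit <- stats::t.test(group_a, group_b, alternative = alternative,
                       var.equal = !welch)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = unname(fit$p.value), direction = observed, degenerate = FALSE)
}

#' One-way ANOVA with Tukey's HSD post hoc test
#'
#' The comparison used for the multi-genotype MRI statistics: a one-way
#' analysis of variance over all groups, followed by Tukey's honestly
#' significant difference test for every pairwise contrast. The adjusted
#' p-values control the family-wise error rate and are never smaller than
#' the corresponding unadjusted pairwise p (computed from the same pooled
#' residual variance).
#'
#' @param table A [group_table()], or a numeric vector (with `groups` given).
#' @param groups Group labels when `table` is a plain vector.
#' @return List with `F`, `df` (numerator, denominator), `p`, and `tukey`,
#'   a data frame of pairwise contrasts (`comparison`, `diff`, `lwr`,
#'   `upr`, `p_unadjusted`, `p_adjusted`). When all observations are
#'   identical the convention `F = 0`, `p = 1` (all Tukey p = 1) is
#'   reported.
#' @examples
#' tab <- group_table(c(1, 2, 3, 7, 8, 9), rep(c("WT", "KO"), each = 3))
#' anova_tukey(tab)
#' @export
anova_tukey <- function(table, groups = NULL) {
  if (inherits(table, "group_table")) {
    values <- table$value
    groups <- table$group
  } else {
    values <- table
    if (is.null(groups)) abort_data("`groups` must be supplied")
    groups <- as.character(groups)
  }
  if (length(values) != length(groups)) {
    abort_data("`values` and `groups` lengths differ")
  }
  counts <- table(groups)
  if (length(counts) < 2L) abort_data("ANOVA needs at least 2 groups")
  if (any(counts < 2L)) {
    abort_data(sprintf("group '%s' has fewer than 2 observations",
                       names(counts)[counts < 2L][1L]))
  }
  g <- factor(groups)
  k <- nlevels(g)
  n <- length(values)
  pairs <- utils::combn(levels(g), 2L)
  pair_names <- sprintf("%s-%s", pairs[2L, ], pairs[1L, ])
  if (all(values == values[1L])) { # totally flat data: no variance to test
    tukey <- data.frame(comparison = pair_names, diff = 0, lwr = 0, upr = 0,
                        p_unadjusted = 1, p_adjusted = 1,
                        stringsAsFactors = FALSE)
    return(list(F = 0, df = c(k - 1L, n - k), p = 1, tukey = tukey))
  }
  fit <- stats::aov(values ~ g)
  an <- summary(fit)[[1L]]
  th <- stats::TukeyHSD(fit)$g
  mse <- an["Residuals", "Mean Sq"]
  df_res <- an["Residuals", "Df"]
  means <- tapply(values, g, mean)
  ns <- tapply(values, g, length)
  p_unadj <- apply(pairs, 2L, function(pr) {
    se <- sqrt(mse * (1 / ns[pr[1L]] + 1 / ns[pr[2L]]))
    tstat <- (means[pr[2L]] - means[pr[1L]]) / se
    2 * stats::pt(-abs(tstat), df_res)
  })
  ord <- match(pair_names, rownames(th))
  tukey <- data.frame(comparison = pair_names,
                      diff = th[ord, "diff"], lwr = th[ord, "lwr"],
                      upr = th[ord, "upr"],
                      p_unadjusted = unname(p_unadj),
                      p_adjusted = th[ord, "p adj"],
                      stringsAsFactors = FALSE)
  rownames(tukey) <- NULL
  list(F = an["g", "F value"], df = c(an["g", "Df"], df_res),
       p = an["g", "Pr(>F)"], tukey = tukey)
}

#' Fold-change filter between late and early cultures
#'
#' Selects modulated genes by the linear-scale ratio of group means,
#' `FC = mean(late) / mean(early)`. A gene is selected when `FC >= threshold`
#' or `FC <= 1/threshold`, boundaries inclusive (so a gene at exactly the
#' threshold counts as modulated, making reported counts reproducible).
#' Genes whose early mean is zero have no finite ratio; they are excluded
#' from selection and reported separately.
#'
#' @param expr An [expression_matrix()].
#' @param threshold Linear fold-change cut-off (> 1), default 1.8.
#' @return List with
#'   `selected` (data frame `gene`, `fc`, `log2_fc`, `direction`, sorted by
#'   decreasing `|log2_fc|`, ties by gene id),
#'   `excluded` (genes with zero early mean), and `n_selected`.
#' @examples
#' em <- simulate_expression_matrix(50, 3, planted_up = list(n = 4, fold = 2),
#'                                  noise_sd_log2 = 0, seed = 1)
#' fold_change_filter(em)$n_selected
#' @export
fold_change_filter <- function(expr, threshold = 1.8) {
  if (!inherits(expr, "expression_matrix")) {
    abort_data("`expr` must be an expression_matrix")
  }
  check_number(threshold, "threshold", lower = 1, strict_lower = TRUE)
  early <- rowMeans(expr$values[, expr$groups == "early", drop = FALSE])
  late <- rowMeans(expr$values[, expr$groups == "late", drop = FALSE])
  zero <- early == 0
  excluded <- data.frame(gene = rownames(expr$values)[zero],
                         reason = rep("zero mean in the early group",
                                      sum(zero)),
                         stringsAsFactors = FALSE)
  fc <- late[!zero] / early[!zero]
  gene <- rownames(expr$values)[!zero]
  keep <- fc >= threshold | fc <= 1 / threshold
  selected <- data.frame(gene = gene[keep], fc = unname(fc[keep]),
                         log2_fc = unname(log2(fc[keep])),
                         direction = ifelse(fc[keep] >= 1, "up", "down"),
                         stringsAsFactors = FALSE)
  selected <- selected[order(-abs(selected$log2_fc), selected$gene), ]
  rownames(selected) <- NULL
  list(selected = selected, excluded = excluded,
       n_selected = nrow(selected), threshold = threshold)
}

#' Per-group mean and standard error
#'
#' @inheritParams anova_tukey
#' @return Data frame with `group`, `n`, `mean`, `sem` and `sem_defined`
#'   (FALSE for singleton groups, where the SEM of 0 is a placeholder).
#' @examples
#' summarize_groups(group_table(c(2, 4, 6), rep("WT", 3)))
#' @export
summarize_groups <- function(table, groups = NULL) {
  if (inherits(table, "group_table")) {
    values <- table$value
    groups <- table$group
  } else {
    values <- table
    if (is.null(groups)) abort_data("`groups` must be supplied")
    groups <- as.character(groups)
  }
  if (length(values) == 0L) abort_data("no measurements given")
  if (length(values) != length(groups)) {
    abort_data("`values` and `groups` lengths differ")
  }
  out <- do.call(rbind, lapply(split(values, groups), function(v) {
    data.frame(n = length(v), mean = mean(v), sem = sem(v),
               sem_defined = length(v) > 1L)
  }))
  out <- cbind(group = rownames(out), out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
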