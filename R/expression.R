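#' Expression matrix with early/late culture groups
#'
#' A genes-by-samples matrix of linear-scale (non-negative) expression
#' values, with each sample assigned to the "early" (days 1.5-2 of culture)
#' or "late" (days 3-5) stage of syncytiotrophoblast differentiation. This
#' is the container the fold-change filter operates on.
#'
#' @param values Numeric matrix, genes in rows (rownames required, unique),
#'   samples in columns, values finite and >= 0.
#' @param groups Character/factor of length `ncol(values)` with levels
#'   `"early"` and `"late"`, each non-empty.
#' @param days Optional numeric vector of culture days per sample.
#' @return An object of class `expression_matrix`.
#' @examples
#' m <- matrix(c(10, 10, 20, 20), nrow = 1,
#'             dimnames = list("g1", paste0("s", 1:4)))
#' expression_matrix(m, groups = c("early", "early", "late", "late"))
#' @export
expression_matrix <- function(values, groups, days = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort_data("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || anyNA(rownames(values)) ||
      any(!nzchar(rownames(values)))) {
    abort_data("every gene (row) must have a non-empty identifier")
  }
  if (anyDuplicated(rownames(values))) {
    abort_data(sprintf("duplicated gene identifier: %s",
                       rownames(values)[duplicated(rownames(values))][1L]))
  }
  if (anyNA(values) || any(!is.finite(values)) || any(values < 0)) {
    abort_data("expression values must be finite and non-negative")
  }
  groups <- as.character(groups)
  if (length(groups) != ncol(values)) {
    abort_data("`groups` must have one entry per sample column")
  }
  if (!all(groups %in% c("early", "late"))) {
    abort_data("groups must be 'early' or 'late'")
  }
  if (!all(c("early", "late") %in% groups)) {
    abort_data("both the early and the late group must be non-empty")
  }
  if (!is.null(days) && length(days) != ncol(values)) {
    abort_data("`days` must have one entry per sample column")
  }
  structure(
    list(values = values, groups = groups, days = days),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples (early n=%d, late n=%d)\n",
              nrow(x$values), ncol(x$values),
              sum(x$groups == "early"), sum(x$groups == "late")))
  invisible(x)
}

#' Simulate an expression matrix with planted fold changes
#'
#' Gene baselines are drawn once on the log2 scale (uniform on 3-10, a
#' realistic microarray dynamic range); the planted "up" genes are shifted
#' by `+log2(fold)` in the late group and the "down" genes by `-log2(fold)`,
#' so their linear-scale group-mean ratios equal the stated fold exactly in
#' the noiseless case. Independent Gaussian log2 noise is then added per
#' cell. Non-planted genes have equal group means in expectation.
#'
#' @param n_genes Number of genes.
#' @param n_per_group Samples per group (early and late).
#' @param planted_up,planted_down Either `NULL`, or a list with elements
#'   `fold` (> 1) and one of `genes` (gene indices or ids) or `n` (a count;
#'   up takes the first `n` genes, down the last `n`). The two sets must be
#'   disjoint.
#' @param noise_sd_log2 Standard deviation of per-cell log2 noise (>= 0).
#' @param seed Integer seed.
#' @return An [expression_matrix()] whose `truth` attribute lists the
#'   planted up/down gene ids and folds.
#' @examples
#' em <- simulate_expression_matrix(100, 4,
#'                                  planted_up = list(n = 5, fold = 2),
#'                                  noise_sd_log2 = 0, seed = 1)
#' attr(em, "truth")$up
#' @export
simulate_expression_matrix <- function(n_genes, n_per_group,
                                       planted_up = NULL,
                                       planted_down = NULL,
                                       noise_sd_log2 = 0.1, seed = 1) {
  n_genes <- check_count(n_genes, "n_genes")
  n_per_group <- check_count(n_per_group, "n_per_group")
  check_number(noise_sd_log2, "noise_sd_log2", lower = 0)
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  up_idx <- resolve_planted(planted_up, gene_ids, side = "up")
  down_idx <- resolve_planted(planted_down, gene_ids, side = "down")
  if (length(intersect(up_idx$idx, down_idx$idx)) > 0L) {
    abort_config("planted up and down gene sets must be disjoint")
  }
  n_samp <- 2L * n_per_group
  groups <- rep(c("early", "late"), each = n_per_group)
  days <- c(rep_len(c(1.5, 2), n_per_group), rep_len(c(3, 5), n_per_group))
  log2_expr <- with_local_seed(seed, {
    base <- stats::runif(n_genes, 3, 10)
    m <- matrix(rep(base, n_samp), nrow = n_genes, ncol = n_samp)
    late <- groups == "late"
    if (length(up_idx$idx)) {
      m[up_idx$idx, late] <- m[up_idx$idx, late] + log2(up_idx$fold)
    }
    if (length(down_idx$idx)) {
      m[down_idx$idx, late] <- m[down_idx$idx, late] - log2(down_idx$fold)
    }
    m + matrix(stats::rnorm(n_genes * n_samp, 0, noise_sd_log2),
               n_genes, n_samp)
  })
  values <- 2^log2_expr
  dimnames(values) <- list(gene_ids, sprintf("%s_%d", groups,
                                             c(seq_len(n_per_group),
                                               seq_len(n_per_group))))
  em <- expression_matrix(values, groups, days = days)
  attr(em, "truth") <- list(up = gene_ids[up_idx$idx],
                            down = gene_ids[down_idx$idx],
                            fold_up = up_idx$fold, fold_down = down_idx$fold)
  em
}

resolve_planted <- function(spec, gene_ids, side) {
  if (is.null(spec)) {
    return(list(idx = integer(0), fold = NA_real_))
  }
  if (!is.list(spec) || is.null(spec$fold)) {
    abort_config(sprintf("planted_%s must be a list with a `fold` element", side))
  }
  check_number(spec$fold, sprintf("planted_%s$fold", side),
               lower = 1, strict_lower = TRUE)
  if (!is.null(spec$genes)) {
    idx <- if (is.character(spec$genes)) {
      match(spec$genes, gene_ids)
    } else {
      as.integer(spec$genes)
    }
    if (anyNA(idx) || any(idx < 1L) || any(idx > length(gene_ids))) {
      abort_config(sprintf("planted_%s$genes contains unknown genes", side))
    }
  } else if (!is.null(spec$n)) {
    n <- check_count(spec$n, sprintf("planted_%s$n", side), lower = 0L)
    if (n > length(gene_ids)) {
      abort_config(sprintf("planted_%s$n exceeds n_genes", side))
    }
    idx <- if (side == "up") seq_len(n) else
      seq.int(length(gene_ids) - n + 1L, length.out = n)
  } else {
    abort_config(sprintf("planted_%s needs `genes` or `n`", side))
  }
  list(idx = unique(idx), fold = spec$fold)
}
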