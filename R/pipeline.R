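#' Pipeline configuration
#'
#' Collects every tunable of the synthetic demo pipeline in one validated
#' object that round-trips losslessly through a YAML file. The defaults
#' reproduce the study conditions the package emulates: 25 scans of 163 s,
#' a five-genotype panel with the weakest recovery in the double knockout,
#' at least 12 counting fields per specimen, and the 1.8-fold expression
#' cut-off.
#'
#' @param seed Global integer seed; all stage seeds are derived from it.
#' @param n_scans,scan_duration Acquisition schedule (see [scan_schedule()]).
#' @param n_per_group Placentas per genotype in the simulated cohort.
#' @param noise_sd Measurement noise of simulated curves (signal units).
#' @param between_placenta_sd Fractional amplitude variability.
#' @param smooth_window Landmark-detection smoothing window (odd).
#' @param fold_threshold Expression fold-change cut-off (> 1).
#' @param intensity_threshold `"otsu"` or a numeric threshold.
#' @param n_fields,syncytia_per_field Histology field structure.
#' @param p_positive Named numeric vector of per-nucleus positivity
#'   probabilities, one per staining condition (e.g. normal vs IUGR-like).
#' @param image_fractions Named numeric vector of planted positive-area
#'   fractions, one image group per name.
#' @param n_genes,expr_n_per_group,n_planted,planted_fold,noise_sd_log2
#'   Expression-simulation settings; `n_planted` genes are planted up and
#'   the same number down at `planted_fold`.
#' @return An object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(seed = 1,
                            n_scans = 25,
                            scan_duration = 163,
                            n_per_group = 8,
                            noise_sd = 2,
                            between_placenta_sd = 0.1,
                            smooth_window = 3,
                            fold_threshold = 1.8,
                            intensity_threshold = "otsu",
                            n_fields = 12,
                            syncytia_per_field = 20,
                            p_positive = c(normal = 0.5, iugr = 0.2),
                            image_fractions = c(WT = 0.40,
                                                Cdkn2a_KO = 0.18,
                                                Cdkn2a_p53_DKO = 0.12),
                            n_genes = 2000,
                            expr_n_per_group = 4,
                            n_planted = 102,
                            planted_fold = 2.0,
                            noise_sd_log2 = 0.1) {
  cfg <- list(seed = seed, n_scans = n_scans, scan_duration = scan_duration,
              n_per_group = n_per_group, noise_sd = noise_sd,
              between_placenta_sd = between_placenta_sd,
              smooth_window = smooth_window, fold_threshold = fold_threshold,
              intensity_threshold = intensity_threshold,
              n_fields = n_fields, syncytia_per_field = syncytia_per_field,
              p_positive = p_positive, image_fractions = image_fractions,
              n_genes = n_genes, expr_n_per_group = expr_n_per_group,
              n_planted = n_planted, planted_fold = planted_fold,
              noise_sd_log2 = noise_sd_log2)
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  check_count(cfg$seed, "seed", lower = 0L)
  check_count(cfg$n_scans, "n_scans", lower = 3L)
  check_number(cfg$scan_duration, "scan_duration", lower = 0,
               strict_lower = TRUE)
  check_count(cfg$n_per_group, "n_per_group")
  check_number(cfg$noise_sd, "noise_sd", lower = 0)
  check_number(cfg$between_placenta_sd, "between_placenta_sd", lower = 0)
  sw <- check_count(cfg$smooth_window, "smooth_window")
  if (sw %% 2L == 0L) abort_config("`smooth_window` must be odd")
  check_number(cfg$fold_threshold, "fold_threshold", lower = 1,
               strict_lower = TRUE)
  if (!identical(cfg$intensity_threshold, "otsu")) {
    check_number(cfg$intensity_threshold, "intensity_threshold")
  }
  check_count(cfg$n_fields, "n_fields")
  check_count(cfg$syncytia_per_field, "syncytia_per_field")
  if (is.null(names(cfg$p_positive)) || any(!nzchar(names(cfg$p_positive)))) {
    abort_config("`p_positive` must be a named vector")
  }
  for (nm in names(cfg$p_positive)) {
    check_number(cfg$p_positive[[nm]], sprintf("p_positive[%s]", nm),
                 lower = 0, upper = 1)
  }
  if (is.null(names(cfg$image_fractions)) ||
      any(!nzchar(names(cfg$image_fractions)))) {
    abort_config("`image_fractions` must be a named vector")
  }
  for (nm in names(cfg$image_fractions)) {
    check_number(cfg$image_fractions[[nm]],
                 sprintf("image_fractions[%s]", nm), lower = 0, upper = 1)
  }
  check_count(cfg$n_genes, "n_genes")
  check_count(cfg$expr_n_per_group, "expr_n_per_group")
  check_count(cfg$n_planted, "n_planted", lower = 0L)
  if (2L * cfg$n_planted > cfg$n_genes) {
    abort_config("2 * n_planted exceeds n_genes")
  }
  check_number(cfg$planted_fold, "planted_fold", lower = 1,
               strict_lower = TRUE)
  check_number(cfg$noise_sd_log2, "noise_sd_log2", lower = 0)
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("<pipeline_config> seed=%d, %d scans x %gs, n_per_group=%d, fold cut %g\n",
              x$seed, x$n_scans, x$scan_duration, x$n_per_group,
              x$fold_threshold))
  invisible(x)
}

#' Read / write a pipeline configuration file (YAML)
#'
#' Unknown keys are rejected; omitted keys fall back to the defaults of
#' [pipeline_config()]. A written configuration reads back identically.
#'
#' @param path YAML file path.
#' @param config A [pipeline_config()].
#' @return `read_pipeline_config()` returns a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort_config(sprintf("unknown configuration key(s): %s",
                         paste(unknown, collapse = ", ")))
  }
  for (nm in c("p_positive", "image_fractions")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  if (!inherits(config, "pipeline_config")) {
    abort_config("`config` must be a pipeline_config")
  }
  out <- unclass(config)
  out$p_positive <- as.list(out$p_positive)
  out$image_fractions <- as.list(out$image_fractions)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run the full synthetic demo pipeline
#'
#' Executes the stages in dependency order — simulate (cohort curves, vena
#' cava reference, syncytia fields, staining images, expression matrix),
#' dynamics (landmark statistics and ROE), quantify (syncytia percentages
#' and image area fractions), compare (ANOVA + Tukey on the MRI statistics,
#' t-test on histology, fold-change filter) — writing every artifact to
#' `out_dir` and finishing with a `manifest.json` listing each output file
#' with its MD5 hash, the seed, the configuration hash and the package
#' version, so any run can be re-created exactly. Per-curve landmark
#' failures are recorded in `dynamics_failures.csv`, not raised.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the manifest as a list.
#' @examples
#' \donttest{
#' out <- file.path(tempdir(), "placentaq-demo")
#' run_pipeline(pipeline_config(n_per_group = 3, n_genes = 200,
#'                              n_planted = 10), out)
#' list.files(out)
#' }
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (!inherits(config, "pipeline_config")) {
    abort_config("`config` must be a pipeline_config")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  add <- function(p) paths[[length(paths) + 1L]] <<- p

  ## stage 1: simulate -------------------------------------------------
  schedule <- scan_schedule(config$n_scans, config$scan_duration)
  presets <- genotype_presets(noise_sd = config$noise_sd,
                              between_placenta_sd = config$between_placenta_sd)
  cohort <- simulate_cohort(presets, config$n_per_group, schedule,
                            seed = sub_seed(config$seed, 1L))
  add(write_curves(cohort, file.path(out_dir, "curves.csv")))
  # blood-pool reference: fast, strong uptake, no recovery limb
  vc <- simulate_si_curve(
    curve_params(baseline = 100, uptake_amplitude = 1.5, uptake_time = 3,
                 recovery_amplitude = 0, recovery_onset = 30,
                 recovery_rate = 0.25, noise_sd = config$noise_sd),
    schedule, seed = sub_seed(config$seed, 2L),
    id = "vena_cava", group = "reference")
  add(write_curves(list(vc), file.path(out_dir, "vena_cava.csv")))

  fields_by_cond <- lapply(seq_along(config$p_positive), function(ci) {
    fields <- simulate_syncytia_fields(
      config$n_fields, config$syncytia_per_field,
      p_nucleus_positive = config$p_positive[[ci]],
      seed = sub_seed(config$seed, 10L + ci))
    for (fi in seq_along(fields)) {
      fields[[fi]]$field_id <- sprintf("%s_%s", names(config$p_positive)[ci],
                                       fields[[fi]]$field_id)
    }
    fields
  })
  names(fields_by_cond) <- names(config$p_positive)
  add(write_fields(unlist(fields_by_cond, recursive = FALSE),
                   file.path(out_dir, "fields.csv")))

  images <- lapply(seq_along(config$image_fractions), function(ii) {
    simulate_intensity_image(
      c(128, 128), config$image_fractions[[ii]],
      seed = sub_seed(config$seed, 20L + ii))
  })
  names(images) <- names(config$image_fractions)
  for (nm in names(images)) {
    add(write_image(images[[nm]],
                    file.path(out_dir, sprintf("image_%s.tif", nm))))
  }

  expr <- simulate_expression_matrix(
    config$n_genes, config$expr_n_per_group,
    planted_up = list(n = config$n_planted, fold = config$planted_fold),
    planted_down = list(n = config$n_planted, fold = config$planted_fold),
    noise_sd_log2 = config$noise_sd_log2, seed = sub_seed(config$seed, 30L))
  add(write_expression(expr, file.path(out_dir, "expression.tsv"),
                       file.path(out_dir, "samples.csv")))
  add(file.path(out_dir, "samples.csv"))

  ## stage 2: dynamics -------------------------------------------------
  dyn <- analyze_cohort(cohort, smooth_window = config$smooth_window)
  add(write_results_csv(dyn$results,
                        file.path(out_dir, "dynamics_results.csv")))
  add(write_results_csv(dyn$failures,
                        file.path(out_dir, "dynamics_failures.csv")))
  roe_rows <- do.call(rbind, lapply(cohort, function(cu) {
    r <- compute_roe(cu, vc)
    data.frame(id = cu$id, interval_start_s = cu$times[-length(cu$times)],
               roe_per_min = r, stringsAsFactors = FALSE)
  }))
  add(write_results_csv(roe_rows, file.path(out_dir, "roe.csv")))

  ## stage 3: quantify -------------------------------------------------
  sync_rows <- do.call(rbind, lapply(names(fields_by_cond), function(cond) {
    pct <- vapply(fields_by_cond[[cond]], percent_positive_syncytia,
                  numeric(1))
    data.frame(condition = cond,
               field_id = vapply(fields_by_cond[[cond]], `[[`,
                                 character(1), "field_id"),
               percent_positive = pct, stringsAsFactors = FALSE)
  }))
  add(write_results_csv(sync_rows, file.path(out_dir, "syncytia_fields.csv")))
  agg <- do.call(rbind, lapply(split(sync_rows, sync_rows$condition),
                               function(d) {
    a <- aggregate_fields(d$percent_positive)
    data.frame(condition = d$condition[1L], n_fields = a$n_fields,
               mean = a$mean, sem = a$sem, stringsAsFactors = FALSE)
  }))
  add(write_results_csv(agg, file.path(out_dir, "syncytia_summary.csv")))

  int_rows <- do.call(rbind, lapply(names(images), function(nm) {
    q <- quantify_intensity(images[[nm]], threshold = config$intensity_threshold)
    data.frame(group = nm, area_fraction = q$area_fraction,
               mean_intensity = q$mean_intensity, threshold = q$threshold,
               stringsAsFactors = FALSE)
  }))
  add(write_results_csv(int_rows, file.path(out_dir, "intensity_results.csv")))

  ## stage 4: compare --------------------------------------------------
  stat_rows <- list()
  for (meas in c("initial_enhancement", "recovery")) {
    at <- anova_tukey(group_table(dyn$results[[meas]], dyn$results$group))
    stat_rows[[length(stat_rows) + 1L]] <- data.frame(
      comparison = sprintf("%s: one-way ANOVA", meas), statistic = at$F,
      p = at$p, adjusted_p = NA_real_, stringsAsFactors = FALSE)
    stat_rows[[length(stat_rows) + 1L]] <- data.frame(
      comparison = sprintf("%s: Tukey %s", meas, at$tukey$comparison),
      statistic = at$tukey$diff, p = at$tukey$p_unadjusted,
      adjusted_p = at$tukey$p_adjusted, stringsAsFactors = FALSE)
  }
  if (length(fields_by_cond) >= 2L) {
    conds <- names(fields_by_cond)[1:2]
    tt <- t_test(sync_rows$percent_positive[sync_rows$condition == conds[1L]],
                 sync_rows$percent_positive[sync_rows$condition == conds[2L]])
    stat_rows[[length(stat_rows) + 1L]] <- data.frame(
      comparison = sprintf("percent positive syncytia: %s vs %s t-test",
                           conds[1L], conds[2L]),
      statistic = tt$t, p = tt$p, adjusted_p = NA_real_,
      stringsAsFactors = FALSE)
  }
  add(write_results_csv(do.call(rbind, stat_rows),
                        file.path(out_dir, "stats.csv")))

  fc <- fold_change_filter(expr, threshold = config$fold_threshold)
  sel_path <- file.path(out_dir, "selected_genes.tsv")
  sel <- fc$selected
  sel$fc <- fmt_num(sel$fc)
  sel$log2_fc <- fmt_num(sel$log2_fc)
  utils::write.table(sel, sel_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  add(sel_path)

  ## manifest ----------------------------------------------------------
  paths <- unique(unlist(paths))
  manifest <- list(
    package = "placentaq",
    version = as.character(utils::packageVersion("placentaq")),
    seed = config$seed,
    config = unclass(config),
    config_md5 = digest_config(config),
    outputs = lapply(paths, function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

digest_config <- function(config) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  write_pipeline_config(config, tmp)
  unname(tools::md5sum(tmp))
}
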