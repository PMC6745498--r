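#' File formats
#'
#' All tabular formats are plain CSV/TSV with a header; floating-point
#' values are written with 6 significant digits, and `read(write(x))`
#' preserves values to that precision. Readers validate the schema strictly
#' and name the offending row or column in their error message. Images are
#' single-channel 32-bit float TIFF with intensities in `[0, 1]`.
#'
#' @name placentaq-io
#' @keywords internal
NULL

fmt_num <- function(x) signif(x, 6)

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort_data(sprintf("%s: missing column(s) %s", path,
                       paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(df), cols)
  if (length(extra)) {
    abort_data(sprintf("%s: unexpected column(s) %s", path,
                       paste(extra, collapse = ", ")))
  }
  df[cols]
}

require_numeric <- function(df, cols, path) {
  for (col in cols) {
    v <- df[[col]]
    if (is.character(v)) {
      suppressWarnings(vn <- as.numeric(v))
    } else {
      vn <- as.numeric(v)
    }
    if (anyNA(vn)) {
      row <- which(is.na(vn))[1L]
      abort_data(sprintf("%s: non-numeric value in column '%s', row %d",
                         path, col, row))
    }
    df[[col]] <- vn
  }
  df
}

#' Write / read SI curves as long-format CSV
#'
#' Columns: `placenta_id`, `group`, `time_s`, `si`; one row per (curve,
#' timepoint). Times must be strictly increasing within each curve.
#'
#' @param curves List of [si_curve()] objects.
#' @param path CSV file path.
#' @return `read_curves()` returns an `si_cohort` list of [si_curve()]s.
#' @export
write_curves <- function(curves, path) {
  rows <- do.call(rbind, lapply(curves, function(cu) {
    data.frame(placenta_id = cu$id, group = cu$group,
               time_s = fmt_num(cu$times), si = fmt_num(cu$values),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_curves
#' @export
read_curves <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  df <- require_columns(df, c("placenta_id", "group", "time_s", "si"), path)
  df <- require_numeric(df, c("time_s", "si"), path)
  curves <- lapply(split(df, factor(df$placenta_id,
                                    levels = unique(df$placenta_id))),
                   function(d) {
    dup <- duplicated(d$time_s)
    if (any(dup)) {
      row <- match(d$time_s[dup][1L], df$time_s[df$placenta_id == d$placenta_id[1L]])
      abort_data(sprintf("%s: duplicated timepoint %g for placenta '%s'",
                         path, d$time_s[dup][1L], d$placenta_id[1L]))
    }
    if (is.unsorted(d$time_s, strictly = TRUE)) {
      abort_data(sprintf("%s: times not strictly increasing for placenta '%s'",
                         path, d$placenta_id[1L]))
    }
    si_curve(d$time_s, d$si, id = d$placenta_id[1L], group = d$group[1L])
  })
  names(curves) <- NULL
  structure(curves, class = c("si_cohort", "list"))
}

#' Write / read syncytia fields as per-nucleus CSV
#'
#' Columns: `field_id`, `syncytium_id`, `nucleus_id`, `positive` (0/1).
#'
#' @param fields List of [syncytia_field()] objects.
#' @param path CSV file path.
#' @return `read_fields()` returns a list of [syncytia_field()]s.
#' @export
write_fields <- function(fields, path) {
  rows <- do.call(rbind, lapply(fields, function(f) {
    do.call(rbind, lapply(seq_along(f$syncytia), function(si) {
      data.frame(field_id = f$field_id, syncytium_id = si,
                 nucleus_id = seq_along(f$syncytia[[si]]),
                 positive = f$syncytia[[si]], stringsAsFactors = FALSE)
    }))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fields
#' @export
read_fields <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  df <- require_columns(df, c("field_id", "syncytium_id", "nucleus_id",
                              "positive"), path)
  df <- require_numeric(df, c("syncytium_id", "nucleus_id", "positive"), path)
  bad <- which(!df$positive %in% c(0, 1))
  if (length(bad)) {
    abort_data(sprintf("%s: column 'positive' must be 0/1 (row %d)",
                       path, bad[1L]))
  }
  lapply(split(df, factor(df$field_id, levels = unique(df$field_id))),
         function(d) {
    syncytia <- lapply(split(d$positive,
                             factor(d$syncytium_id,
                                    levels = unique(d$syncytium_id))),
                       as.integer)
    names(syncytia) <- NULL
    syncytia_field(d$field_id[1L], syncytia)
  })
}

#' Write / read a single-channel intensity image as TIFF
#'
#' 32-bit float, single channel; intensities must lie in `[0, 1]` (the
#' package's image convention). An optional mask is written alongside as a
#' second TIFF.
#'
#' @param image An [intensity_image()].
#' @param path TIFF file path.
#' @param mask_path Optional mask TIFF path (read side).
#' @param channel Channel label to attach on read.
#' @return `read_image()` returns an [intensity_image()].
#' @export
write_image <- function(image, path) {
  px <- image$pixels
  if (any(px < 0) || any(px > 1)) {
    abort_data("image intensities must lie in [0, 1] for TIFF export")
  }
  tiff::writeTIFF(px, path, bits.per.sample = 32)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path, mask_path = NULL, channel = "SA-b-gal") {
  if (!file.exists(path)) abort_data(sprintf("file not found: %s", path))
  px <- tiff::readTIFF(path)
  if (length(dim(px)) != 2L) {
    abort_data(sprintf("%s: expected a single-channel image", path))
  }
  mask <- NULL
  if (!is.null(mask_path)) {
    if (!file.exists(mask_path)) {
      abort_data(sprintf("file not found: %s", mask_path))
    }
    mask <- tiff::readTIFF(mask_path) > 0.5
  }
  intensity_image(px, mask = mask, channel = channel)
}

#' Write / read an expression matrix as TSV plus sample sheet
#'
#' The TSV has genes in rows (first column `gene`) and one column per
#' sample; the sample sheet CSV has columns `sample`, `group`, `day`.
#'
#' @param expr An [expression_matrix()].
#' @param path TSV file path for the matrix.
#' @param samples_path CSV file path for the sample sheet.
#' @return `read_expression()` returns an [expression_matrix()].
#' @export
write_expression <- function(expr, path, samples_path) {
  df <- data.frame(gene = rownames(expr$values),
                   fmt_num(expr$values), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  sheet <- data.frame(sample = colnames(expr$values), group = expr$groups,
                      day = if (is.null(expr$days)) NA else expr$days,
                      stringsAsFactors = FALSE)
  utils::write.csv(sheet, samples_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path, samples_path) {
  for (p in c(path, samples_path)) {
    if (!file.exists(p)) abort_data(sprintf("file not found: %s", p))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1L] != "gene") {
    abort_data(sprintf("%s: first column must be 'gene'", path))
  }
  genes <- df$gene
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!vapply(df[-1L], is.numeric, logical(1)))[1L]
    abort_data(sprintf("%s: non-numeric values in column '%s'",
                       path, names(df)[-1L][bad]))
  }
  rownames(mat) <- genes
  sheet <- utils::read.csv(samples_path, stringsAsFactors = FALSE)
  sheet <- require_columns(sheet, c("sample", "group", "day"), samples_path)
  if (!identical(colnames(mat), sheet$sample)) {
    abort_data(sprintf("%s: samples do not match the matrix columns",
                       samples_path))
  }
  days <- suppressWarnings(as.numeric(sheet$day))
  expression_matrix(mat, sheet$group,
                    days = if (anyNA(days)) NULL else days)
}

# Generic numeric results writer used by the pipeline: every numeric column
# rounded to 6 significant digits, no quoting, deterministic order.
write_results_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
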