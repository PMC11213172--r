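#' Read a methylation dataset from delimited files
#'
#' Loads a probes-by-samples value matrix (CSV or TSV, gzip-aware; first
#' column = probe IDs) together with a sample sheet (CSV with columns
#' `sample_id`, `group`, optional `batch`). The value scale is taken from
#' `scale`, or inferred: any value above 1 means percent, otherwise beta
#' (M-values must be declared explicitly). Samples present in the matrix but
#' missing from the sheet are dropped with a warning; sheet samples missing
#' from the matrix are an error.
#'
#' @param matrix_path Path to the value matrix.
#' @param sheet_path Path to the sample sheet CSV.
#' @param scale `"percent"`, `"beta"`, `"mvalue"`, or `NULL` to infer.
#' @return A [methyl_dataset()].
#' @export
read_methyl_dataset <- function(matrix_path, sheet_path, scale = NULL) {
  delim <- if (grepl("\\.csv(\\.gz)?$", matrix_path)) "," else "\t"
  tbl <- readr::read_delim(matrix_path,
    delim = delim, show_col_types = FALSE,
    progress = FALSE
  )
  names(tbl)[1] <- "probe_id"
  sheet <- readr::read_csv(sheet_path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample_id", "group") %in% names(sheet))) {
    rlang::abort("Sample sheet needs `sample_id` and `group` columns.")
  }
  matrix_samples <- setdiff(names(tbl), "probe_id")
  unknown <- setdiff(sheet$sample_id, matrix_samples)
  if (length(unknown) > 0) {
    rlang::abort(sprintf(
      "Sample sheet rows with no matrix column: %s.",
      paste(unknown, collapse = ", ")
    ))
  }
  extra <- setdiff(matrix_samples, sheet$sample_id)
  if (length(extra) > 0) {
    rlang::warn(sprintf(
      "%d matrix column(s) not in the sample sheet were dropped: %s.",
      length(extra), paste(utils::head(extra, 5), collapse = ", ")
    ))
    tbl <- tbl[, c("probe_id", sheet$sample_id)]
  }
  vals <- as.matrix(tbl[, setdiff(names(tbl), "probe_id")])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(
      tbl[setdiff(names(tbl), "probe_id")],
      is.numeric, logical(1)
    ))
    rlang::abort(sprintf(
      "Non-numeric values in column(s): %s.",
      paste(names(bad), collapse = ", ")
    ))
  }
  if (is.null(scale)) {
    scale <- if (max(vals, na.rm = TRUE) > 1 || min(vals, na.rm = TRUE) < 0) {
      "percent"
    } else {
      "beta"
    }
    message(sprintf("Inferred value scale: %s.", scale))
  }
  ds <- methyl_dataset(tbl, sheet, scale = scale)
  bad_cell <- which(!is.finite(methyl_values(ds)) &
    !is.na(methyl_values(ds)), arr.ind = TRUE)
  ds
}

#' Write a methylation dataset to disk
#'
#' Writes the value matrix as gzipped TSV (probes in rows, header of sample
#' IDs) and the sample sheet as CSV.
#'
#' @param data A [methyl_dataset()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix (default `"methylome"`).
#' @return Invisibly, the paths written.
#' @export
write_methyl_dataset <- function(data, dir, prefix = "methylome") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  matrix_path <- file.path(dir, paste0(prefix, "_matrix.tsv.gz"))
  sheet_path <- file.path(dir, paste0(prefix, "_samples.csv"))
  readr::write_tsv(tibble::as_tibble(data), matrix_path, progress = FALSE)
  readr::write_csv(sample_info(data), sheet_path, progress = FALSE)
  invisible(c(matrix = matrix_path, sheet = sheet_path))
}
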