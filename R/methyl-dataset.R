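#' Methylation dataset container
#'
#' A `methyl_dataset` is a tibble with a `probe_id` column followed by one
#' numeric column per sample, carrying two attributes: `samples`, a tibble
#' describing each sample (`sample_id`, `group`, and optionally `batch`), and
#' `scale`, one of `"percent"`, `"beta"` or `"mvalue"` declaring the unit of
#' the stored values. All pipeline verbs take a `methyl_dataset` first and
#' return one (or a plain tibble for reports), so stages chain with the pipe.
#'
#' @param values Numeric matrix, probes in rows and samples in columns, with
#'   row and column names; or a data frame with a `probe_id` column.
#' @param samples A data frame with columns `sample_id`, `group` and
#'   optionally `batch`. `sample_id` must match the value columns.
#' @param scale One of `"percent"`, `"beta"`, `"mvalue"`. Percent values must
#'   lie in \[0, 100\], beta values in \[0, 1\]; M-values are unconstrained.
#' @param seed Optional integer recorded as metadata when the dataset was
#'   generated from a seeded simulation.
#'
#' @return A `methyl_dataset` tibble.
#' @export
#' @examples
#' m <- matrix(runif(12), 3, 4,
#'   dimnames = list(paste0("p", 1:3), paste0("s", 1:4))
#' )
#' sheet <- tibble::tibble(
#'   sample_id = colnames(m),
#'   group = rep(c("control", "positive"), each = 2)
#' )
#' methyl_dataset(m, sheet, scale = "beta")
methyl_dataset <- function(values, samples, scale = c("percent", "beta", "mvalue"),
                           seed = NULL) {
  scale <- rlang::arg_match(scale)
  samples <- tibble::as_tibble(samples)
  if (!all(c("sample_id", "group") %in% names(samples))) {
    rlang::abort("`samples` needs columns `sample_id` and `group`.")
  }
  if (is.matrix(values)) {
    if (is.null(rownames(values)) || is.null(colnames(values))) {
      rlang::abort("`values` matrix must have probe row names and sample column names.")
    }
    out <- tibble::as_tibble(as.data.frame(values),
      .name_repair = "minimal"
    )
    out <- tibble::add_column(out, probe_id = rownames(values), .before = 1)
  } else {
    out <- tibble::as_tibble(values)
    if (!"probe_id" %in% names(out)) {
      rlang::abort("`values` data frame must contain a `probe_id` column.")
    }
    out <- dplyr::relocate(out, "probe_id")
  }
  new_methyl_dataset(out, samples, scale, seed = seed, validate = TRUE)
}

# Low-level constructor; `validate = FALSE` skips range scans on large
# matrices whose values are guaranteed by construction.
new_methyl_dataset <- function(tbl, samples, scale, seed = NULL, validate = TRUE) {
  attr(tbl, "samples") <- samples
  attr(tbl, "scale") <- scale
  attr(tbl, "seed") <- seed
  class(tbl) <- c("methyl_dataset", class(tibble::tibble()))
  if (validate) validate_methyl_dataset(tbl)
  tbl
}

validate_methyl_dataset <- function(x) {
  samples <- sample_info(x)
  value_cols <- setdiff(names(x), "probe_id")
  if (!setequal(value_cols, samples$sample_id) ||
    anyDuplicated(samples$sample_id) > 0) {
    rlang::abort("Sample sheet `sample_id`s must match the value columns exactly.")
  }
  if (anyDuplicated(x$probe_id) > 0) {
    rlang::abort("Duplicate probe IDs are not allowed.")
  }
  if (anyNA(samples$group)) {
    rlang::abort("Every sample needs a group label.")
  }
  rng <- suppressWarnings(range(methyl_values(x), na.rm = TRUE))
  lim <- switch(methyl_scale(x),
    percent = c(0, 100),
    beta = c(0, 1),
    mvalue = c(-Inf, Inf)
  )
  if (is.finite(rng[1]) && (rng[1] < lim[1] || rng[2] > lim[2])) {
    rlang::abort(sprintf(
      "Values outside [%g, %g] are invalid on the %s scale.",
      lim[1], lim[2], methyl_scale(x)
    ))
  }
  invisible(x)
}

#' Accessors for methyl_dataset components
#'
#' @param x A [methyl_dataset()].
#' @return `methyl_values()` returns the probe-by-sample numeric matrix,
#'   `sample_info()` the sample sheet tibble, `methyl_scale()` the scale tag,
#'   `n_probes()`/`n_samples()` the dimensions, and `group_labels()` the group
#'   label of each sample in column order.
#' @export
methyl_values <- function(x) {
  stopifnot(inherits(x, "methyl_dataset"))
  m <- as.matrix(as.data.frame(x)[, setdiff(names(x), "probe_id"), drop = FALSE])
  rownames(m) <- x$probe_id
  m
}

#' @rdname methyl_values
#' @export
sample_info <- function(x) attr(x, "samples")

#' @rdname methyl_values
#' @export
methyl_scale <- function(x) attr(x, "scale")

#' @rdname methyl_values
#' @export
n_probes <- function(x) nrow(x)

#' @rdname methyl_values
#' @export
n_samples <- function(x) nrow(sample_info(x))

#' @rdname methyl_values
#' @export
group_labels <- function(x) {
  samples <- sample_info(x)
  samples$group[match(setdiff(names(x), "probe_id"), samples$sample_id)]
}

# Row-subset a dataset by probe IDs (keeps attributes intact).
subset_probes <- function(x, probe_ids) {
  keep <- x$probe_id %in% probe_ids
  out <- x[keep, , drop = FALSE]
  new_methyl_dataset(out, sample_info(x), methyl_scale(x),
    seed = attr(x, "seed"), validate = FALSE
  )
}

# Replace the value matrix, keeping probe order and metadata.
set_values <- function(x, m, scale = methyl_scale(x)) {
  tbl <- tibble::as_tibble(as.data.frame(m), .name_repair = "minimal")
  tbl <- tibble::add_column(tbl, probe_id = rownames(m), .before = 1)
  new_methyl_dataset(tbl, sample_info(x), scale,
    seed = attr(x, "seed"), validate = FALSE
  )
}

#' @export
print.methyl_dataset <- function(x, ...) {
  groups <- table(sample_info(x)$group)
  cat(sprintf(
    "<methyl_dataset> %d probes x %d samples [%s scale]\n",
    n_probes(x), n_samples(x), methyl_scale(x)
  ))
  cat(
    "groups:",
    paste(sprintf("%s (%d)", names(groups), as.integer(groups)), collapse = ", "),
    "\n"
  )
  NextMethod()
}
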