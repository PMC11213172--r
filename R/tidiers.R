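#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-round history of a selection
#'
#' @param x A `methyl_selection` from [select_probes()].
#' @param ... Unused.
#' @return One row per round: probes scored, Otsu threshold, probes kept,
#'   dip statistic and p-value.
#' @method tidy methyl_selection
#' @export
tidy.methyl_selection <- function(x, ...) {
  purrr::imap_dfr(x$rounds, function(r, i) {
    tibble::tibble(
      round = i,
      n_probes = nrow(r$score_table),
      otsu_threshold = r$otsu_threshold,
      n_kept = length(r$kept_probes),
      dip_statistic = r$dip_statistic,
      dip_p = r$dip_p
    )
  })
}

#' @rdname tidy.methyl_selection
#' @method glance methyl_selection
#' @export
glance.methyl_selection <- function(x, ...) {
  tibble::tibble(
    n_rounds = length(x$rounds),
    n_probes_start = nrow(x$rounds[[1]]$score_table),
    n_probes_pre_vif = length(x$final_probes_pre_vif),
    n_probes_final = length(x$final_probes),
    model = x$config$model,
    comparison = x$config$comparison,
    n_iterations = x$config$n_iterations
  )
}

#' Tidy per-iteration F1 scores of a performance bootstrap
#'
#' @param x A `methyl_performance` from [performance_bootstrap()].
#' @param ... Unused.
#' @return A tibble with one row per retained iteration.
#' @method tidy methyl_performance
#' @export
tidy.methyl_performance <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$f1), f1 = x$f1)
}

#' @rdname tidy.methyl_performance
#' @method glance methyl_performance
#' @export
glance.methyl_performance <- function(x, ...) {
  tibble::tibble(
    median_f1 = x$median_f1,
    mean_f1 = mean(x$f1),
    fraction_perfect = x$fraction_perfect,
    n_iterations = x$n_iterations,
    n_retained = length(x$f1),
    model = x$model,
    comparison = x$comparison,
    n_probes = length(x$probes)
  )
}

#' One-row summary of a validation run
#'
#' @param x A `methyl_validation` from [run_validation_workflow()].
#' @param ... Unused.
#' @return A tibble with per-tier detection counts and run metadata.
#' @method glance methyl_validation
#' @export
glance.methyl_validation <- function(x, ...) {
  d <- x$detection
  tibble::tibble(
    n_background = x$n_background,
    n_prefiltered = x$n_prefiltered,
    n_rounds = length(x$selection$rounds),
    n_selected = length(x$selection$final_probes),
    high_detected = d$n_detected[d$tier == "high"],
    medium_detected = d$n_detected[d$tier == "medium"],
    low_detected = d$n_detected[d$tier == "low"],
    false_positives = d$n_detected[d$tier == "background"],
    seed = x$seed
  )
}
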