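#' End-to-end synthetic validation workflow
#'
#' Chains the full pipeline on a freshly generated synthetic methylome:
#' generate background and planted signal probes, screen with the biomarker
#' prefilter, convert to M-values, drop non-finite rows, run the iterated
#' bootstrap/Otsu/dip selection (binary comparison), and score the final
#' probe set against the planted truth. Every stage is logged with probe
#' counts and wall time.
#'
#' @param n_background Background probes (default one million).
#' @param n_per_group Samples per group (default 25).
#' @param specs Signal tiers, see [default_signal_specs()].
#' @param prefilter A [prefilter_config()].
#' @param selection A [selection_config()]; the default runs 500 bootstrap
#'   iterations with a radial SVM (the full-scale analysis uses 10,000).
#' @param seed Integer seed; the whole run is deterministic given it.
#' @param out_dir Optional directory: when given, the truth table, prefilter
#'   report, score tables, selected probes, detection report and a
#'   provenance record are written there.
#' @return A `methyl_validation` object: `detection` (tibble from
#'   [score_detection()]), `selection` (`methyl_selection`), `truth`,
#'   `n_prefiltered`, `timings` and the configuration.
#' @export
#' @examples
#' \donttest{
#' run <- run_validation_workflow(n_background = 1000, seed = 7,
#'   selection = selection_config(n_iterations = 50))
#' run$detection
#' }
run_validation_workflow <- function(n_background = 1e6, n_per_group = 25,
                                    specs = default_signal_specs(),
                                    prefilter = prefilter_config(),
                                    selection = selection_config(
                                      n_iterations = 500,
                                      comparison = "binary",
                                      model = "svm_rbf"
                                    ),
                                    seed, out_dir = NULL) {
  t_all <- proc.time()[3]
  timings <- c()
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    value <- force(expr)
    timings[[name]] <<- proc.time()[3] - t0
    message(sprintf("[%s] done in %.1fs", name, timings[[name]]))
    value
  }
  withr::local_seed(seed)
  gen <- stage("simulate", generate_validation_dataset(
    n_background = n_background, n_per_group = n_per_group,
    specs = specs, seed = sample.int(.Machine$integer.max, 1)
  ))
  message(sprintf(
    "[simulate] %d probes x %d samples", n_probes(gen$dataset),
    n_samples(gen$dataset)
  ))
  kept <- stage("prefilter", biomarker_prefilter(gen$dataset, prefilter))
  mv <- stage(
    "mvalues",
    drop_nonfinite(suppressMessages(to_mvalues(kept)))
  )
  sel <- stage("select", select_probes(mv, selection,
    seed = sample.int(.Machine$integer.max, 1)
  ))
  detection <- score_detection(sel, gen$truth)
  timings[["total"]] <- proc.time()[3] - t_all
  out <- structure(
    list(
      detection = detection,
      selection = sel,
      truth = gen$truth,
      n_prefiltered = n_probes(kept),
      prefilter_config = prefilter,
      selection_config = selection,
      n_background = n_background,
      n_per_group = n_per_group,
      seed = seed,
      timings = timings
    ),
    class = "methyl_validation"
  )
  if (!is.null(out_dir)) write_validation_artifacts(out, kept, out_dir)
  out
}

write_validation_artifacts <- function(run, kept, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(run$truth, file.path(out_dir, "truth_table.csv"))
  rep <- prefilter_report(kept)
  if (!is.null(rep)) {
    readr::write_csv(
      rep[rep$kept, , drop = FALSE],
      file.path(out_dir, "prefilter_kept.csv")
    )
  }
  readr::write_csv(run$detection, file.path(out_dir, "detection_report.csv"))
  writeLines(
    run$selection$final_probes,
    file.path(out_dir, "selected_probes.txt")
  )
  readr::write_csv(
    tidy(run$selection),
    file.path(out_dir, "selection_rounds.csv")
  )
  jsonlite::write_json(
    list(
      package_version = as.character(utils::packageVersion("methylsieve")),
      seed = run$seed,
      n_background = run$n_background,
      n_per_group = run$n_per_group,
      prefilter = unclass(run$prefilter_config),
      selection = unclass(run$selection_config[
        setdiff(names(run$selection_config), "plan")
      ])
    ),
    file.path(out_dir, "provenance.json"),
    auto_unbox = TRUE, null = "null"
  )
  invisible(out_dir)
}

#' @export
print.methyl_validation <- function(x, ...) {
  cat(sprintf(
    "<methyl_validation> seed %s, %g background probes, %d prefiltered, %d selected\n",
    format(x$seed), x$n_background, x$n_prefiltered,
    length(x$selection$final_probes)
  ))
  print(x$detection)
  invisible(x)
}
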