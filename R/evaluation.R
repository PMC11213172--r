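#' Post-selection performance bootstrap
#'
#' Repeatedly splits the data with the stratified plan, fits the classifier
#' on the training rows restricted to the selected probes, and records the
#' weighted one-vs-rest F1 on the held-out samples. No p-values are computed
#' in this phase; the probe set is fixed. Because the F1 distribution is
#' typically non-normal, the median over iterations is the headline summary,
#' together with the fraction of iterations achieving a perfect score.
#'
#' @param data A [methyl_dataset()] on the M-value scale.
#' @param probes Character vector of probe IDs to use as features.
#' @param model `"svm_rbf"`, `"svm_linear"` or `"lda"`.
#' @param comparison `"binary"` or `"four_class"` (controls class labels and
#'   the default split plan, as in [selection_config()]).
#' @param n_iterations Number of bootstrap splits (default 1000).
#' @param plan Optional split plan; defaults as in [bootstrap_scores()].
#' @param positive_groups As in [selection_config()], for binary comparison
#'   on multi-group data.
#' @param cost SVM regularization constant.
#' @param seed Optional integer seed.
#' @return A `methyl_performance` object: the per-iteration F1 values with
#'   `median_f1`, `fraction_perfect`, model kind and comparison mode.
#' @export
performance_bootstrap <- function(data, probes,
                                  model = c("svm_rbf", "svm_linear", "lda"),
                                  comparison = c("binary", "four_class"),
                                  n_iterations = 1000, plan = NULL,
                                  positive_groups = NULL, cost = 1,
                                  seed = NULL) {
  model <- rlang::arg_match(model)
  comparison <- rlang::arg_match(comparison)
  if (length(probes) == 0) rlang::abort("`probes` must be non-empty.")
  if (!all(probes %in% data$probe_id)) {
    rlang::abort("Some `probes` are absent from the dataset.")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  sub <- subset_probes(data, probes)
  groups <- group_labels(sub)
  cmp <- resolve_comparison(
    groups,
    selection_config(
      comparison = comparison,
      positive_groups = positive_groups
    ),
    need_contrast = FALSE
  )
  plan <- plan %||% proportional_split_plan(
    groups,
    min_test = if (comparison == "four_class") 2 else NULL
  )
  check_plan(plan, groups)
  X <- methyl_values(sub)
  f1s <- rep(NA_real_, n_iterations)
  for (it in seq_len(n_iterations)) {
    sp <- split_indices(groups, plan)
    fit <- tryCatch(
      fit_classifier(
        t(X[, sp$train, drop = FALSE]), cmp$model_labels[sp$train],
        kind = model, cost = cost
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    pred <- predict(fit, t(X[, sp$test, drop = FALSE]))
    f1s[it] <- weighted_ovr_f1(cmp$model_labels[sp$test], pred)
  }
  f1s <- f1s[!is.na(f1s)]
  if (length(f1s) == 0) rlang::abort("Every bootstrap iteration failed.")
  structure(
    list(
      f1 = f1s,
      median_f1 = stats::median(f1s),
      fraction_perfect = mean(f1s == 1),
      n_iterations = n_iterations,
      model = model,
      comparison = comparison,
      probes = probes
    ),
    class = "methyl_performance"
  )
}

#' @export
print.methyl_performance <- function(x, ...) {
  cat(sprintf(
    "<methyl_performance> %s, %s: median F1 %.3f (%.1f%% perfect) over %d iterations, %d probes\n",
    x$model, x$comparison, x$median_f1, 100 * x$fraction_perfect,
    x$n_iterations, length(x$probes)
  ))
  invisible(x)
}

#' Sensitivity of a trained model to widening sample variance
#'
#' Trains the classifier once on the full dataset restricted to the probe
#' set, then challenges it with synthetic test sets drawn uniformly on
#' `[mu - A sigma, mu + A sigma]` per probe and group
#' ([generate_sensitivity_samples()]), where `mu` and `sigma` are estimated
#' from the training data and `A` sweeps the grid. The median weighted
#' one-vs-rest F1 over replicate draws is recorded for every `A`: at `A = 0`
#' all synthetic samples sit exactly at their group means, while large `A`
#' floods the decision boundary with off-distribution samples.
#'
#' @inheritParams performance_bootstrap
#' @param A_grid Width multipliers (default `1:10`).
#' @param n_per_group Synthetic samples per group per replicate (default 30).
#' @param n_replicates Replicate synthetic draws per `A` (default 20).
#' @return A `methyl_sensitivity` tibble: `A`, `median_f1`, `q25`, `q75`,
#'   with the model kind as an attribute.
#' @export
sensitivity_curve <- function(data, probes,
                              model = c("svm_rbf", "svm_linear", "lda"),
                              comparison = c("binary", "four_class"),
                              A_grid = 1:10, n_per_group = 30,
                              n_replicates = 20, positive_groups = NULL,
                              cost = 1, seed = NULL) {
  model <- rlang::arg_match(model)
  comparison <- rlang::arg_match(comparison)
  if (length(A_grid) == 0) rlang::abort("`A_grid` must be non-empty.")
  if (any(A_grid < 0)) rlang::abort("`A_grid` must be non-negative.")
  if (!is.null(seed)) withr::local_seed(seed)
  sub <- subset_probes(data, probes)
  groups <- group_labels(sub)
  cmp <- resolve_comparison(
    groups,
    selection_config(comparison = comparison, positive_groups = positive_groups),
    need_contrast = FALSE
  )
  X <- methyl_values(sub)
  fit <- fit_classifier(t(X), cmp$model_labels, kind = model, cost = cost)
  # per-probe per-group moments on the model's class labels
  moments <- purrr::map_dfr(unique(cmp$model_labels), function(lab) {
    cols <- which(cmp$model_labels == lab)
    tibble::tibble(
      probe_id = rownames(X),
      group = lab,
      mu = rowMeans(X[, cols, drop = FALSE]),
      sigma = row_sds(X[, cols, drop = FALSE])
    )
  })
  rows <- purrr::map_dfr(sort(A_grid), function(A) {
    f1s <- vapply(seq_len(n_replicates), function(r) {
      syn <- generate_sensitivity_samples(moments, A, n_per_group)
      pred <- predict(fit, t(methyl_values(syn)))
      weighted_ovr_f1(group_labels(syn), pred)
    }, numeric(1))
    tibble::tibble(
      A = A,
      median_f1 = stats::median(f1s),
      q25 = stats::quantile(f1s, 0.25, names = FALSE),
      q75 = stats::quantile(f1s, 0.75, names = FALSE)
    )
  })
  attr(rows, "model") <- model
  attr(rows, "comparison") <- comparison
  attr(rows, "n_replicates") <- n_replicates
  class(rows) <- c("methyl_sensitivity", class(rows))
  rows
}

#' Score a selection against the planted truth
#'
#' Counts how many planted probes of each discriminability tier appear in the
#' final selected set, and how many background probes were selected (false
#' positives).
#'
#' @param selection A `methyl_selection` object or a character vector of
#'   selected probe IDs.
#' @param truth Tibble `probe_id`/`tier` as produced by
#'   [generate_validation_dataset()].
#' @return A tibble `tier`, `n_planted`, `n_detected` (the `background` row
#'   counts false positives).
#' @export
score_detection <- function(selection, truth) {
  probes <- if (inherits(selection, "methyl_selection")) {
    selection$final_probes
  } else {
    as.character(selection)
  }
  missing <- setdiff(probes, truth$probe_id)
  if (length(missing) > 0) {
    rlang::abort(sprintf(
      "Selected probe(s) missing from the truth table: %s.",
      paste(utils::head(missing, 5), collapse = ", ")
    ))
  }
  tiers <- c("high", "medium", "low", "background")
  truth$tier <- factor(truth$tier, levels = tiers)
  sel <- truth$probe_id %in% probes
  out <- tibble::tibble(
    tier = tiers,
    n_planted = as.integer(table(truth$tier)[tiers]),
    n_detected = as.integer(table(truth$tier[sel])[tiers])
  )
  out$n_detected[is.na(out$n_detected)] <- 0L
  out
}

#' PCA with one group projected post hoc
#'
#' Fits a principal component analysis (sample-centered, unscaled M-values)
#' on all samples except those of `heldout_group`, then centers the held-out
#' samples with the same means and projects them onto the fitted axes. Used
#' when one cohort is too small to contribute stable variance estimates but
#' should still be displayed in the ordination.
#'
#' @param data A [methyl_dataset()].
#' @param probes Optional probe subset (default: all probes).
#' @param heldout_group Group label to exclude from the fit, or `NULL` for an
#'   ordinary PCA.
#' @param n_components Number of components to return (default 3).
#' @return A `methyl_pca` tibble: `sample_id`, `group`, `heldout`, `PC1..k`;
#'   attribute `explained_variance` holds the per-component variance
#'   fractions (of the fitting samples).
#' @export
pca_project_heldout <- function(data, probes = NULL, heldout_group = NULL,
                                n_components = 3) {
  if (!is.null(probes)) data <- subset_probes(data, probes)
  if (n_probes(data) < n_components) {
    rlang::abort("Fewer probes than requested components.")
  }
  X <- t(methyl_values(data)) # samples x probes
  g <- group_labels(data)
  held <- if (is.null(heldout_group)) {
    rep(FALSE, nrow(X))
  } else {
    if (!heldout_group %in% g) rlang::abort("`heldout_group` not present.")
    g == heldout_group
  }
  if (sum(!held) < 2) rlang::abort("Need at least 2 fitting samples.")
  pc <- stats::prcomp(X[!held, , drop = FALSE], center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  scores <- matrix(NA_real_, nrow(X), k)
  scores[!held, ] <- pc$x[, seq_len(k), drop = FALSE]
  if (any(held)) {
    centered <- sweep(X[held, , drop = FALSE], 2, pc$center)
    scores[held, ] <- centered %*% pc$rotation[, seq_len(k), drop = FALSE]
  }
  out <- tibble::as_tibble(as.data.frame(scores), .name_repair = "minimal")
  names(out) <- paste0("PC", seq_len(k))
  out <- tibble::add_column(out,
    sample_id = rownames(X), group = g,
    heldout = held, .before = 1
  )
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  attr(out, "explained_variance") <- ev[seq_len(k)]
  class(out) <- c("methyl_pca", class(out))
  out
}
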