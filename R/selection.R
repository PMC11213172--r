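#' Selection configuration
#'
#' All tunable constants of the probe-selection loop in one object. The
#' defaults mirror the published procedure: 10,000 stratified bootstrap
#' iterations, a false-discovery-rate gate of 0.001 on the per-iteration
#' F-tests, at least 2 gated probes for an iteration to count, a dip-test
#' stopping rule at alpha 0.05, and a pairwise variance-inflation-factor
#' limit of 5 for the final pruning.
#'
#' @param n_iterations Bootstrap iterations per scoring round.
#' @param fdr_gate Benjamini-Hochberg q-value threshold a probe must clear in
#'   an iteration to enter that iteration's model.
#' @param min_probes_per_iteration Minimum number of gated probes; iterations
#'   below this are discarded (a model needs more than one feature).
#' @param dip_alpha Significance level of the dip-test stopping rule.
#' @param dip_n_null Monte-Carlo null samples for each dip test.
#' @param vif_limit Pairwise variance-inflation-factor limit; for any pair
#'   exceeding it only the higher-scoring probe is kept.
#' @param comparison `"binary"` (presence/absence of the condition) or
#'   `"four_class"` (all four cohorts as separate classes).
#' @param model `"svm_rbf"` or `"lda"`; the classifier scored in every
#'   iteration.
#' @param cost SVM regularization constant.
#' @param plan Optional split plan (see [proportional_split_plan()]); when
#'   `NULL` a plan is derived from the group sizes: 80% training per group,
#'   rounded, with every group keeping at least 2 test samples in four-class
#'   mode.
#' @param positive_groups For binary comparison on data with more than two
#'   groups: the group labels pooled into the positive class.
#' @param contrast For four-class comparison: the two group labels entering
#'   the per-iteration F-test (only two groups can feed an F statistic; the
#'   remaining cohorts still participate in model fitting and scoring).
#' @param score_denominator `"usable"` divides summed scores by the number of
#'   non-discarded iterations (discarded iterations are removed outright);
#'   `"all"` divides by `n_iterations`.
#' @param seed Integer seed making the whole selection deterministic.
#' @return A `selection_config` list.
#' @export
selection_config <- function(n_iterations = 10000, fdr_gate = 0.001,
                             min_probes_per_iteration = 2, dip_alpha = 0.05,
                             dip_n_null = 2000, vif_limit = 5,
                             comparison = c("binary", "four_class"),
                             model = c("svm_rbf", "lda"), cost = 1,
                             plan = NULL, positive_groups = NULL,
                             contrast = NULL,
                             score_denominator = c("usable", "all"),
                             seed = NULL) {
  comparison <- rlang::arg_match(comparison)
  model <- rlang::arg_match(model)
  score_denominator <- rlang::arg_match(score_denominator)
  if (fdr_gate <= 0 || fdr_gate >= 1) rlang::abort("`fdr_gate` must be in (0, 1).")
  if (vif_limit <= 1) rlang::abort("`vif_limit` must exceed 1.")
  if (n_iterations < 1) rlang::abort("`n_iterations` must be at least 1.")
  structure(
    list(
      n_iterations = as.integer(n_iterations), fdr_gate = fdr_gate,
      min_probes_per_iteration = as.integer(min_probes_per_iteration),
      dip_alpha = dip_alpha, dip_n_null = as.integer(dip_n_null),
      vif_limit = vif_limit, comparison = comparison, model = model,
      cost = cost, plan = plan, positive_groups = positive_groups,
      contrast = contrast, score_denominator = score_denominator,
      seed = seed
    ),
    class = "selection_config"
  )
}

#' Stratified train/test split plans
#'
#' A split plan is a tibble with columns `group`, `n_train`, `n_test` whose
#' per-group totals match the data. `proportional_split_plan()` assigns each
#' group `round(train_frac * n)` training samples; `min_test` forces at least
#' that many test samples per group (used in four-class mode so that every
#' cohort, however small, is represented in testing).
#'
#' @param groups Character vector of group labels, one per sample (or a
#'   [methyl_dataset()]).
#' @param train_frac Training fraction (default 0.8).
#' @param min_test Minimum test samples per group, or `NULL`.
#' @return A tibble `group`, `n_train`, `n_test`.
#' @export
#' @examples
#' cohort <- rep(c("control", "cp", "epilepsy", "cp_epilepsy"), c(8, 10, 4, 8))
#' proportional_split_plan(cohort) # 23 train / 7 test
#' proportional_split_plan(cohort, min_test = 2) # 22 train / 8 test
proportional_split_plan <- function(groups, train_frac = 0.8, min_test = NULL) {
  if (inherits(groups, "methyl_dataset")) groups <- group_labels(groups)
  tab <- table(groups)
  n_train <- round(train_frac * as.integer(tab))
  n_test <- as.integer(tab) - n_train
  if (!is.null(min_test)) {
    bump <- pmax(min_test - n_test, 0)
    n_train <- n_train - bump
    n_test <- n_test + bump
  }
  if (any(n_train < 1)) {
    rlang::abort("Every group needs at least 1 training sample under this plan.")
  }
  tibble::tibble(
    group = names(tab),
    n_train = as.integer(n_train), n_test = as.integer(n_test)
  )
}

check_plan <- function(plan, groups) {
  tab <- table(groups)
  if (!setequal(plan$group, names(tab))) {
    rlang::abort("Split plan groups do not match the data's groups.")
  }
  sizes <- as.integer(tab[plan$group])
  if (any(plan$n_train + plan$n_test != sizes) ||
    any(plan$n_train < 0) || any(plan$n_test < 0)) {
    rlang::abort("Split plan totals must match the group sizes.")
  }
  invisible(plan)
}

# Fast index split used inside the bootstrap: returns integer indices.
split_indices <- function(groups, plan) {
  train <- integer(0)
  test <- integer(0)
  for (r in seq_len(nrow(plan))) {
    idx <- which(groups == plan$group[r])
    tr <- if (plan$n_train[r] > 0) sample(idx, plan$n_train[r]) else integer(0)
    rest <- setdiff(idx, tr)
    te <- if (length(rest) > plan$n_test[r]) {
      sample(rest, plan$n_test[r])
    } else {
      rest
    }
    train <- c(train, tr)
    test <- c(test, te)
  }
  list(train = train, test = test)
}

#' Draw one stratified train/test split
#'
#' Samples, within every group, the planned number of training samples
#' without replacement; the remainder forms the test set (capped at the
#' planned test count).
#'
#' @param data A [methyl_dataset()] (or a character vector of group labels
#'   named by sample ID).
#' @param plan A split plan (see [proportional_split_plan()]); defaults to
#'   the proportional 80/20 plan.
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return A tibble `sample_id`, `group`, `role` (`"train"` or `"test"`).
#' @export
stratified_split <- function(data, plan = NULL, seed = NULL) {
  if (inherits(data, "methyl_dataset")) {
    groups <- group_labels(data)
    ids <- setdiff(names(data), "probe_id")
  } else {
    groups <- as.character(data)
    ids <- names(data) %||% as.character(seq_along(data))
  }
  if (is.null(plan)) plan <- proportional_split_plan(groups)
  check_plan(plan, groups)
  if (!is.null(seed)) withr::local_seed(seed)
  sp <- split_indices(groups, plan)
  tibble::tibble(
    sample_id = c(ids[sp$train], ids[sp$test]),
    group = c(groups[sp$train], groups[sp$test]),
    role = rep(c("train", "test"), c(length(sp$train), length(sp$test)))
  )
}

# Vectorized two-group one-way ANOVA over probe rows.
# X: probes x samples matrix; X2: elementwise square (precomputed);
# i1, i2: column indices of the two groups. Returns list(statistic, p_value).
row_f_stats <- function(X, X2, i1, i2) {
  n1 <- length(i1)
  n2 <- length(i2)
  e1 <- numeric(ncol(X))
  e1[i1] <- 1
  e2 <- numeric(ncol(X))
  e2[i2] <- 1
  s1 <- unname(drop(X %*% e1))
  s2 <- unname(drop(X %*% e2))
  q1 <- unname(drop(X2 %*% e1))
  q2 <- unname(drop(X2 %*% e2))
  m1 <- s1 / n1
  m2 <- s2 / n2
  ssw <- (q1 - n1 * m1 * m1) + (q2 - n2 * m2 * m2)
  msw <- ssw / (n1 + n2 - 2)
  msb <- (n1 * n2 / (n1 + n2)) * (m1 - m2)^2
  f <- msb / msw
  p <- stats::pf(f, 1, n1 + n2 - 2, lower.tail = FALSE)
  # degenerate rows: no within-group variance
  zero_w <- msw <= .Machine$double.eps * pmax(abs(m1) + abs(m2), 1)
  if (any(zero_w)) {
    zero_b <- msb <= .Machine$double.eps * pmax(abs(m1) + abs(m2), 1)
    f[zero_w & !zero_b] <- Inf
    p[zero_w & !zero_b] <- 0
    f[zero_w & zero_b] <- 0
    p[zero_w & zero_b] <- 1
  }
  list(statistic = f, p_value = p, degenerate = zero_w)
}

#' Per-probe two-group F-test
#'
#' One-way ANOVA of each probe between two groups (identical to the squared
#' pooled-variance two-sample t-test, with degrees of freedom 1 and n - 2),
#' vectorized over all probes.
#'
#' @param data A [methyl_dataset()] on the M-value scale.
#' @param contrast Length-2 character: the two group labels to compare
#'   (defaults to the dataset's two groups).
#' @param samples Optional character vector of sample IDs to restrict to
#'   (e.g. a training set).
#' @return A tibble `probe_id`, `statistic`, `p_value`, `degenerate` (no
#'   within-group variance; `p_value` forced to 0 or 1).
#' @export
f_test <- function(data, contrast = NULL, samples = NULL) {
  g <- group_labels(data)
  ids <- setdiff(names(data), "probe_id")
  keep <- if (is.null(samples)) seq_along(ids) else match(samples, ids)
  if (anyNA(keep)) rlang::abort("Unknown sample IDs in `samples`.")
  if (is.null(contrast)) {
    contrast <- unique(g[keep])
    if (length(contrast) != 2) {
      rlang::abort("Specify `contrast`: the data has more than two groups.")
    }
  }
  i1 <- keep[g[keep] == contrast[1]]
  i2 <- keep[g[keep] == contrast[2]]
  if (length(i1) < 2 || length(i2) < 2) {
    rlang::abort("Each contrast group needs at least 2 samples.")
  }
  X <- methyl_values(data)
  res <- row_f_stats(X, X * X, i1, i2)
  tibble::tibble(
    probe_id = data$probe_id,
    statistic = res$statistic,
    p_value = res$p_value,
    degenerate = res$degenerate
  )
}

#' Per-probe informativeness score of one iteration
#'
#' The score a probe receives in an iteration where it clears the FDR gate:
#' the model's weighted one-vs-rest F1 on the held-out samples times the
#' negative decimal log of the probe's own uncorrected F-test p-value.
#'
#' @param f1 Weighted one-vs-rest F1 in \[0, 1\].
#' @param p Uncorrected p-value in (0, 1\].
#' @return `f1 * -log10(p)`.
#' @export
#' @examples
#' probe_score(1, 1e-3) # 3
#' probe_score(0.8, 1e-5) # 4
probe_score <- function(f1, p) {
  f1 * -log10(pmax(p, .Machine$double.xmin))
}

# Resolve comparison semantics against the dataset's groups. Returns:
#   model_labels: per-sample class labels for the classifier
#   contrast_groups: the two labels of `strata` entering the F-test
#   strata: per-sample labels used for the F-test contrast
resolve_comparison <- function(groups, config, need_contrast = TRUE) {
  u <- sort(unique(groups))
  if (config$comparison == "binary") {
    if (length(u) == 2) {
      labels <- groups
      contrast <- u
    } else {
      pos <- config$positive_groups
      if (is.null(pos)) {
        rlang::abort(
          "Binary comparison on >2 groups needs `positive_groups` in the config."
        )
      }
      labels <- ifelse(groups %in% pos, "positive", "negative")
      contrast <- c("negative", "positive")
    }
    list(model_labels = labels, strata = labels, contrast_groups = contrast)
  } else {
    contrast <- config$contrast
    if (need_contrast &&
      (is.null(contrast) || length(contrast) != 2 || !all(contrast %in% u))) {
      rlang::abort(
        "Four-class comparison needs `contrast`, two of the data's group labels."
      )
    }
    list(model_labels = groups, strata = groups, contrast_groups = contrast)
  }
}

# One bootstrap iteration. Returns NULL when discarded, else a list with the
# candidate row indices (ordered by probe ID), their scores and the F1.
iteration_pass <- function(X, X2, probe_ids, groups, cmp, plan, config) {
  sp <- split_indices(groups, plan)
  train <- sp$train
  test <- sp$test
  i1 <- train[cmp$strata[train] == cmp$contrast_groups[1]]
  i2 <- train[cmp$strata[train] == cmp$contrast_groups[2]]
  if (length(i1) < 2 || length(i2) < 2) {
    return(NULL)
  }
  ft <- row_f_stats(X, X2, i1, i2)
  cand <- bh_reject(ft$p_value, config$fdr_gate)
  if (length(cand) < config$min_probes_per_iteration) {
    return(NULL)
  }
  cand <- cand[order(probe_ids[cand])] # invariant to probe row order
  fit <- tryCatch(
    fit_classifier(
      t(X[cand, train, drop = FALSE]), cmp$model_labels[train],
      kind = config$model, cost = config$cost
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(NULL)
  }
  pred <- predict(fit, t(X[cand, test, drop = FALSE]))
  f1 <- weighted_ovr_f1(cmp$model_labels[test], pred)
  list(
    candidates = cand,
    scores = probe_score(f1, ft$p_value[cand]),
    p_values = ft$p_value[cand],
    f1 = f1
  )
}

#' Bootstrap probe scoring
#'
#' Runs `n_iterations` independent stratified splits. In each iteration an
#' F-test contrasts the two comparison groups over the training samples, the
#' p-values are Benjamini-Hochberg corrected over all probes currently under
#' consideration, and probes with q-values below the FDR gate become that
#' iteration's candidate set. A classifier trained on the candidates is
#' scored on the held-out samples and every candidate receives
#' [probe_score()] with its own uncorrected p-value. Iterations with fewer
#' than `min_probes_per_iteration` candidates (or a failed model fit) are
#' discarded outright. A probe's mean score averages over the retained
#' iterations, counting 0 whenever the probe was not a candidate.
#'
#' @param data A [methyl_dataset()] on the M-value scale.
#' @param config A [selection_config()].
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return A `methyl_score_table`: tibble `probe_id`, `mean_score`,
#'   `n_selected`, `mean_p_uncorrected`, with attributes `n_iterations`,
#'   `n_usable`, `mean_f1`.
#' @export
bootstrap_scores <- function(data, config = selection_config(), seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  if (methyl_scale(data) != "mvalue") {
    rlang::warn("Scoring usually runs on M-values; got another scale.")
  }
  groups <- group_labels(data)
  cmp <- resolve_comparison(groups, config)
  plan <- config$plan %||% proportional_split_plan(
    groups,
    min_test = if (config$comparison == "four_class") 2 else NULL
  )
  check_plan(plan, groups)
  X <- methyl_values(data)
  X2 <- X * X
  n_probes <- nrow(X)
  score_sum <- numeric(n_probes)
  n_selected <- integer(n_probes)
  p_sum <- numeric(n_probes)
  f1_sum <- 0
  n_usable <- 0L
  for (it in seq_len(config$n_iterations)) {
    res <- iteration_pass(X, X2, data$probe_id, groups, cmp, plan, config)
    if (is.null(res)) next
    n_usable <- n_usable + 1L
    f1_sum <- f1_sum + res$f1
    score_sum[res$candidates] <- score_sum[res$candidates] + res$scores
    n_selected[res$candidates] <- n_selected[res$candidates] + 1L
    p_sum[res$candidates] <- p_sum[res$candidates] + res$p_values
  }
  if (n_usable == 0L) {
    rlang::abort(paste(
      "All bootstrap iterations were discarded (no iteration had",
      config$min_probes_per_iteration, "probes past the FDR gate).",
      "Consider a larger `fdr_gate`."
    ))
  }
  denom <- if (config$score_denominator == "usable") {
    n_usable
  } else {
    config$n_iterations
  }
  out <- tibble::tibble(
    probe_id = data$probe_id,
    mean_score = score_sum / denom,
    n_selected = n_selected,
    mean_p_uncorrected = ifelse(n_selected > 0, p_sum / pmax(n_selected, 1), NA_real_)
  )
  attr(out, "n_iterations") <- config$n_iterations
  attr(out, "n_usable") <- n_usable
  attr(out, "mean_f1") <- f1_sum / n_usable
  class(out) <- c("methyl_score_table", class(out))
  out
}

#' Prune collinear probes by pairwise variance-inflation factor
#'
#' Scans probes from highest to lowest score; a probe is dropped when its
#' pairwise VIF `1 / (1 - r^2)` with any already-kept probe exceeds
#' `vif_limit`. By default `r` is the pooled within-group correlation of the
#' two probes (computed on residuals after removing group means): collinear
#' probes carry no extra information over and above the group signal they
#' share, and two independently informative probes always correlate strongly
#' across pooled samples purely through that shared group effect, so the raw
#' all-sample correlation (available via `use = "overall"`) would prune
#' genuinely complementary biomarkers. Zero-variance probes have undefined
#' correlations and are dropped with a warning.
#'
#' @param data A [methyl_dataset()] restricted to (or containing) the scored
#'   probes.
#' @param scores Named numeric vector of scores, or a `methyl_score_table`.
#' @param vif_limit VIF threshold (default 5).
#' @param use `"within_group"` (default) or `"overall"` correlation.
#' @return Character vector of kept probe IDs in descending score order.
#' @export
#' @examples
#' # r = 0.8 between two probes gives VIF 2.78: both kept at the default limit
vif_prune <- function(data, scores, vif_limit = 5,
                      use = c("within_group", "overall")) {
  use <- rlang::arg_match(use)
  if (inherits(scores, "methyl_score_table") || is.data.frame(scores)) {
    scores <- stats::setNames(scores$mean_score, scores$probe_id)
  }
  scores <- scores[!is.na(scores)]
  ids <- intersect(names(scores), data$probe_id)
  ids <- ids[order(-scores[ids], ids)] # descending score, ties by ID
  if (length(ids) == 0) rlang::abort("No scored probes to prune.")
  X <- methyl_values(subset_probes(data, ids))
  X <- X[ids, , drop = FALSE]
  if (use == "within_group") {
    g <- group_labels(data)
    for (grp in unique(g)) {
      cols <- g == grp
      X[, cols] <- X[, cols, drop = FALSE] -
        rowMeans(X[, cols, drop = FALSE])
    }
  }
  sds <- row_sds(X)
  if (any(sds == 0)) {
    rlang::warn(sprintf(
      "Dropping %d zero-variance probe(s) with undefined correlation.",
      sum(sds == 0)
    ))
    ids <- ids[sds > 0]
    X <- X[ids, , drop = FALSE]
  }
  if (length(ids) <= 1) {
    return(ids)
  }
  r <- stats::cor(t(X))
  kept <- character(0)
  for (id in ids) {
    if (length(kept) > 0) {
      vifs <- 1 / (1 - r[id, kept]^2)
      if (any(vifs > vif_limit)) next
    }
    kept <- c(kept, id)
  }
  kept
}

#' Iterated probe selection
#'
#' The full selection loop. Round 1 bootstrap-scores all probes and extracts
#' the upper Otsu class of the mean-score distribution; while the dip test
#' finds that extracted score distribution multimodal at `dip_alpha`, the
#' bootstrap (including its FDR correction, now over the reduced probe set)
#' is re-run on the extracted subset and the extraction repeated. When the
#' dip test no longer rejects unimodality the surviving set is pruned for
#' collinearity with [vif_prune()].
#'
#' @param data A [methyl_dataset()] on the M-value scale.
#' @param config A [selection_config()].
#' @param seed Optional integer seed; overrides `config$seed`.
#' @return A `methyl_selection` object: per-round history (`rounds`), the
#'   pre- and post-VIF probe sets, and the configuration. See
#'   [tidy.methyl_selection()].
#' @export
select_probes <- function(data, config = selection_config(), seed = NULL) {
  seed <- seed %||% config$seed
  if (!is.null(seed)) withr::local_seed(seed)
  current <- data
  rounds <- list()
  final <- NULL
  repeat {
    st <- bootstrap_scores(current, config)
    if (length(unique(st$mean_score)) < 2) {
      # point-mass score distribution: nothing to threshold
      final <- st$probe_id[st$mean_score > 0]
      rounds[[length(rounds) + 1]] <- list(
        score_table = st, otsu_threshold = NA_real_,
        kept_probes = final, dip_statistic = NA_real_, dip_p = NA_real_
      )
      break
    }
    ot <- otsu_threshold(st$mean_score)
    upper <- st$probe_id[ot$in_upper]
    upper_scores <- st$mean_score[ot$in_upper]
    dp <- if (length(unique(upper_scores)) >= 4) {
      dip_test(upper_scores, n_null = config$dip_n_null)
    } else {
      list(statistic = NA_real_, p_value = 1)
    }
    rounds[[length(rounds) + 1]] <- list(
      score_table = st, otsu_threshold = ot$threshold,
      kept_probes = upper, dip_statistic = dp$statistic, dip_p = dp$p_value
    )
    if (length(upper) < 2) {
      rlang::warn("Otsu subset collapsed below 2 probes; keeping the current set.")
      final <- current$probe_id
      break
    }
    if (dp$p_value < config$dip_alpha && length(upper) < n_probes(current)) {
      current <- subset_probes(current, upper)
    } else {
      final <- upper
      break
    }
  }
  last <- rounds[[length(rounds)]]$score_table
  scores <- stats::setNames(last$mean_score, last$probe_id)[final]
  pruned <- if (length(final) > 0) {
    vif_prune(subset_probes(data, final), scores, config$vif_limit)
  } else {
    character(0)
  }
  structure(
    list(
      rounds = rounds,
      final_probes_pre_vif = final,
      final_probes = pruned,
      config = config,
      seed = seed
    ),
    class = "methyl_selection"
  )
}

#' @export
print.methyl_selection <- function(x, ...) {
  cat(sprintf(
    "<methyl_selection> %d round(s); %d probe(s) pre-VIF, %d final\n",
    length(x$rounds), length(x$final_probes_pre_vif), length(x$final_probes)
  ))
  for (i in seq_along(x$rounds)) {
    r <- x$rounds[[i]]
    cat(sprintf(
      "  round %d: %d scored -> %d above Otsu threshold %.3g (dip p = %.3g)\n",
      i, nrow(r$score_table), length(r$kept_probes),
      r$otsu_threshold, r$dip_p
    ))
  }
  invisible(x)
}
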