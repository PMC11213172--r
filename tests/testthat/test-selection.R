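test_that("split plans reproduce the cohort stratification", {
  cohort <- rep(
    c("control", "cp", "epilepsy", "cp_epilepsy"),
    c(8, 10, 4, 8)
  )
  binary <- proportional_split_plan(cohort)
  expect_equal(sum(binary$n_train), 23)
  expect_equal(sum(binary$n_test), 7)
  expect_equal(binary$n_train[binary$group == "epilepsy"], 3L)
  four <- proportional_split_plan(cohort, min_test = 2)
  expect_equal(sum(four$n_train), 22)
  expect_equal(sum(four$n_test), 8)
  expect_equal(
    four$n_train[match(
      c("control", "cp", "epilepsy", "cp_epilepsy"),
      four$group
    )],
    c(6L, 8L, 2L, 6L)
  )
  expect_true(all(four$n_test == 2))
})

test_that("stratified splits are disjoint, exhaustive and plan-conforming", {
  cohort <- rep(c("a", "b"), c(12, 8))
  names(cohort) <- sprintf("s%02d", 1:20)
  plan <- proportional_split_plan(cohort)
  sp <- stratified_split(cohort, plan, seed = 4)
  expect_setequal(sp$sample_id, names(cohort))
  expect_equal(sum(sp$role == "train"), sum(plan$n_train))
  expect_equal(anyDuplicated(sp$sample_id), 0L)
  # all-test plan
  plan0 <- tibble::tibble(group = c("a", "b"), n_train = 0L, n_test = c(12L, 8L))
  sp0 <- stratified_split(cohort, plan0, seed = 1)
  expect_equal(sum(sp0$role == "train"), 0)
  # mismatched plan errors
  bad <- tibble::tibble(group = c("a", "b"), n_train = c(5L, 5L), n_test = c(5L, 5L))
  expect_error(stratified_split(cohort, bad, seed = 1), "totals")
})

test_that("the F-test matches hand ANOVA and the squared-t identity", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 1)
  ds <- make_dataset(m, rep(c("a", "b"), each = 3))
  ft <- f_test(ds)
  expect_equal(ft$statistic, 13.5) # hand ANOVA: MSB 13.5, MSW 1
  expect_equal(ft$p_value, pf(13.5, 1, 4, lower.tail = FALSE))
  expect_equal(ft$p_value, 0.0213, tolerance = 1e-3)
  # identical groups: F = 0, p = 1
  m2 <- matrix(rep(c(1, 2, 3), 2), nrow = 1)
  expect_equal(f_test(make_dataset(m2, rep(c("a", "b"), each = 3)))$p_value, 1)
  # F equals t^2 and p-values agree with t.test on 100 random probes
  withr::with_seed(31, X <- matrix(rnorm(100 * 14), 100, 14))
  ds3 <- make_dataset(X, rep(c("a", "b"), each = 7))
  ft3 <- f_test(ds3)
  for (i in seq_len(100)) {
    tt <- t.test(X[i, 1:7], X[i, 8:14], var.equal = TRUE)
    expect_equal(ft3$statistic[i], unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(ft3$p_value[i], tt$p.value, tolerance = 1e-10)
  }
  # and with aov on a handful
  for (i in 1:5) {
    a <- summary(aov(X[i, ] ~ rep(c("a", "b"), each = 7)))[[1]]
    expect_equal(ft3$statistic[i], a[["F value"]][1], tolerance = 1e-10)
  }
})

test_that("degenerate within-group variance is flagged", {
  m <- rbind(
    sep = c(1, 1, 1, 2, 2, 2), # zero within, nonzero between
    const = rep(3, 6) # zero everywhere
  )
  ds <- make_dataset(m, rep(c("a", "b"), each = 3))
  ft <- f_test(ds)
  expect_equal(ft$p_value, c(0, 1))
  expect_true(all(ft$degenerate))
})

test_that("the iteration score follows F1 * -log10(p)", {
  expect_equal(probe_score(1, 1e-3), 3)
  expect_equal(probe_score(0.8, 1e-5), 4)
  expect_equal(probe_score(0, 1e-8), 0)
  expect_true(is.finite(probe_score(1, 0))) # p floored, never infinite
})

test_that("Otsu matches trivial cases and the exhaustive oracle", {
  res <- otsu_threshold(c(0, 0, 0, 10, 10, 10))
  expect_gt(res$threshold, 0)
  expect_lt(res$threshold, 10)
  expect_equal(sum(res$in_upper), 3)
  expect_equal(sum(otsu_threshold(c(1, 2, 100))$in_upper), 1)
  withr::with_seed(17, {
    for (i in 1:200) {
      x <- switch(sample(3, 1),
        runif(sample(5:60, 1)),
        c(rnorm(10), rnorm(sample(3:10, 1), 8)),
        round(runif(sample(5:30, 1)), 1) # ties
      )
      if (length(unique(x)) < 2) next
      expect_equal(otsu_threshold(x)$threshold, otsu_oracle(x))
    }
  })
  expect_error(otsu_threshold(rep(3, 5)), "distinct")
})

test_that("the dip statistic matches the LP oracle on small samples", {
  withr::with_seed(23, {
    for (i in 1:15) {
      x <- round(runif(sample(4:9, 1)), 5)
      expect_equal(dip_stat(x), dip_lp_oracle(x), tolerance = 1e-7)
    }
    # clearly bimodal small sample
    x <- c(0.1, 0.11, 0.12, 0.9, 0.91, 0.92)
    expect_equal(dip_stat(x), dip_lp_oracle(x), tolerance = 1e-7)
  })
})

test_that("every sample respects the 1/(2n) dip lower bound", {
  withr::with_seed(29, {
    for (i in 1:50) {
      n <- sample(4:200, 1)
      x <- switch(sample(3, 1), runif(n), rnorm(n), rexp(n))
      expect_gte(dip_stat(x), 1 / (2 * n) - 1e-12)
    }
  })
  # evenly spaced points achieve the bound exactly
  expect_equal(dip_stat(1:20), 1 / 40)
})

test_that("dip test calibration: uniform null retained, point mixture rejected", {
  withr::with_seed(37, {
    ps <- replicate(40, dip_test(runif(200), n_null = 500)$p_value)
  })
  expect_gte(mean(ps > 0.05), 0.9)
  withr::with_seed(38, {
    x <- c(rep(0, 50), rep(1, 50)) + rnorm(100, 0, 1e-3)
    expect_lt(dip_test(x, n_null = 500)$p_value, 0.05)
  })
  expect_error(dip_test(c(1, 1, 2, 2)), "4 distinct")
})

test_that("VIF pruning keeps r = 0.8 pairs and drops r = 0.9 pairs", {
  for (r in c(0.8, 0.9)) {
    m <- make_correlated_pair(r)
    ds <- make_dataset(m, rep("g", ncol(m))) # one group: within == overall
    kept <- vif_prune(ds, c(p1 = 2, p2 = 1), vif_limit = 5)
    if (r == 0.8) {
      expect_setequal(kept, c("p1", "p2")) # VIF 2.78
    } else {
      expect_identical(kept, "p1") # VIF 5.26: lower-scoring p2 dropped
    }
  }
  # zero-variance probe dropped with a warning
  m2 <- rbind(make_correlated_pair(0.3), p3 = rep(1, 40))
  ds2 <- make_dataset(m2, rep("g", 40))
  expect_warning(
    kept2 <- vif_prune(ds2, c(p1 = 3, p2 = 2, p3 = 1)),
    "zero-variance"
  )
  expect_setequal(kept2, c("p1", "p2"))
})

test_that("within-group VIF ignores correlation induced by the group effect", {
  # two independent probes, both with a strong group difference
  withr::with_seed(41, {
    g <- rep(c("a", "b"), each = 20)
    shift <- ifelse(g == "b", 5, 0)
    m <- rbind(
      p1 = rnorm(40, 0, 0.5) + shift,
      p2 = rnorm(40, 0, 0.5) + shift
    )
    colnames(m) <- sprintf("s%02d", 1:40)
  })
  expect_gt(abs(cor(m[1, ], m[2, ])), 0.894) # pooled correlation is spurious
  ds <- make_dataset(m, g)
  expect_setequal(vif_prune(ds, c(p1 = 2, p2 = 1)), c("p1", "p2"))
  expect_identical(vif_prune(ds, c(p1 = 2, p2 = 1), use = "overall"), "p1")
})

test_that("bootstrap scores behave at the margins", {
  ds <- make_two_group_mvalues(
    n_probes = 12, n_signal = 3, n_per_group = 10,
    delta = 4, sd = 0.4, seed = 51
  )
  cfg <- selection_config(n_iterations = 30, model = "lda")
  st <- bootstrap_scores(ds, cfg, seed = 5)
  expect_s3_class(st, "methyl_score_table")
  expect_true(all(st$mean_score >= 0))
  expect_true(all(st$n_selected <= attr(st, "n_usable")))
  # noise probes that never clear the gate score exactly 0
  expect_true(all(st$mean_score[st$n_selected == 0] == 0))
  # signal probes clear it essentially always
  expect_true(all(st$n_selected[1:3] > 25))
  # a single-iteration run returns that iteration's scores unaveraged
  st1 <- bootstrap_scores(ds, selection_config(n_iterations = 1, model = "lda"),
    seed = 9
  )
  expect_lte(attr(st1, "n_usable"), 1)
})

test_that("bootstrap scoring is invariant to probe row order", {
  ds <- make_two_group_mvalues(n_probes = 15, n_signal = 3, seed = 61)
  cfg <- selection_config(n_iterations = 25)
  st <- bootstrap_scores(ds, cfg, seed = 7)
  perm <- withr::with_seed(1, sample(n_probes(ds)))
  dsp <- methylsieve:::new_methyl_dataset(
    ds[perm, ], sample_info(ds), "mvalue",
    validate = FALSE
  )
  stp <- bootstrap_scores(dsp, cfg, seed = 7)
  expect_equal(
    stp$mean_score[match(st$probe_id, stp$probe_id)],
    st$mean_score
  )
})

test_that("an impossible FDR gate aborts with advice", {
  ds <- make_two_group_mvalues(
    n_probes = 10, n_signal = 0, n_per_group = 4,
    seed = 71
  )
  expect_error(
    bootstrap_scores(ds, selection_config(n_iterations = 5, fdr_gate = 1e-8),
      seed = 1
    ),
    "fdr_gate"
  )
})

test_that("selection keeps strong probes, shrinks monotonically, prunes VIF last", {
  ds <- make_two_group_mvalues(
    n_probes = 40, n_signal = 4, n_per_group = 12,
    delta = 4, sd = 0.5, seed = 81
  )
  cfg <- selection_config(n_iterations = 60, dip_n_null = 300, model = "lda")
  sel <- select_probes(ds, cfg, seed = 3)
  expect_s3_class(sel, "methyl_selection")
  expect_setequal(sel$final_probes, c("p001", "p002", "p003", "p004"))
  expect_true(all(sel$final_probes %in% sel$final_probes_pre_vif))
  td <- tidy(sel)
  expect_true(all(diff(td$n_probes) < 0) || nrow(td) == 1)
  # every selected probe was scored positive at least once
  last <- sel$rounds[[length(sel$rounds)]]$score_table
  expect_true(all(last$mean_score[last$probe_id %in% sel$final_probes] > 0))
  expect_true(all(last$n_selected[last$probe_id %in% sel$final_probes] >= 1))
})

test_that("two strongly discriminative probes survive in a single round", {
  ds <- make_two_group_mvalues(
    n_probes = 2, n_signal = 2, n_per_group = 10,
    delta = 5, sd = 0.3, seed = 91
  )
  cfg <- selection_config(n_iterations = 20, model = "lda")
  # the Otsu class cannot shrink below 2 probes: the current set is kept
  expect_warning(sel <- select_probes(ds, cfg, seed = 2), "current set")
  expect_setequal(sel$final_probes, c("p001", "p002"))
  expect_equal(length(sel$rounds), 1L)
})
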