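test_that("background probes are uniform on [0,100], balanced and seeded", {
  bg <- generate_background(n_probes = 500, n_per_group = 4, seed = 11)
  expect_equal(dim(methyl_values(bg)), c(500, 8))
  expect_true(all(methyl_values(bg) >= 0 & methyl_values(bg) <= 100))
  expect_equal(unname(table(group_labels(bg))["control"]), 4L)
  expect_equal(methyl_scale(bg), "percent")
  # trivial single-probe case stays in bounds
  tiny <- generate_background(1, 2, seed = 1)
  expect_equal(dim(methyl_values(tiny)), c(1, 4))
  expect_true(all(methyl_values(tiny) >= 0 & methyl_values(tiny) <= 100))
  # same seed reproduces bit-identical values
  again <- generate_background(n_probes = 500, n_per_group = 4, seed = 11)
  expect_identical(methyl_values(bg), methyl_values(again))
  expect_error(generate_background(0, 4, seed = 1), "n_probes")
  expect_error(generate_background(10, 1, seed = 1), "n_per_group")
})

test_that("large uniform background matches the analytic mean of U(0,100)", {
  bg <- generate_background(n_probes = 20000, n_per_group = 25, seed = 5)
  expect_equal(mean(methyl_values(bg)), 50, tolerance = 0.1 / 50)
})

test_that("signal probes land in their stated difference and SD ranges", {
  sig <- generate_signal_probes(default_signal_specs(), n_per_group = 25, seed = 3)
  expect_equal(nrow(sig$truth), 30)
  expect_equal(
    as.vector(table(sig$truth$tier)[c("high", "medium", "low")]),
    c(5L, 10L, 15L)
  )
  m <- methyl_values(sig$dataset)
  g <- group_labels(sig$dataset)
  diffs <- abs(rowMeans(m[, g == "control"]) - rowMeans(m[, g == "positive"]))
  # tolerance ~ 4 sd of the observed difference (sd = s_max * sqrt(2/25))
  ranges <- list(high = c(25, 40), medium = c(15, 30), low = c(10, 20))
  s_max <- c(high = 8, medium = 10, low = 12)
  for (tier in names(ranges)) {
    idx <- sig$truth$tier == tier
    tol <- 4 * s_max[[tier]] * sqrt(2 / 25)
    expect_true(all(diffs[idx] >= ranges[[tier]][1] - tol &
      diffs[idx] <= ranges[[tier]][2] + tol), label = tier)
  }
  expect_true(all(m >= 0 & m <= 100))
})

test_that("signal generation converges to the drawn moments at large n", {
  spec <- signal_spec("medium", c(15, 30), c(8, 10), 3)
  sig <- generate_signal_probes(spec, n_per_group = 1e4, seed = 8)
  m <- methyl_values(sig$dataset)
  g <- group_labels(sig$dataset)
  for (grp in c("control", "positive")) {
    sds <- apply(m[, g == grp, drop = FALSE], 1, sd)
    expect_true(all(sds >= 8 - 0.5 & sds <= 10 + 0.5))
  }
  diffs <- abs(rowMeans(m[, g == "control"]) - rowMeans(m[, g == "positive"]))
  expect_true(all(diffs >= 15 - 0.5 & diffs <= 30 + 0.5))
})

test_that("zero-SD tier gives constant groups at exactly the drawn difference", {
  spec <- signal_spec("high", c(25, 40), c(0, 0), 2)
  sig <- generate_signal_probes(spec, n_per_group = 5, seed = 4)
  m <- methyl_values(sig$dataset)
  g <- group_labels(sig$dataset)
  expect_true(all(apply(m[, g == "control"], 1, sd) == 0))
  d <- abs(rowMeans(m[, g == "control"]) - rowMeans(m[, g == "positive"]))
  expect_true(all(d >= 25 & d <= 40))
})

test_that("infeasible tier placement errors", {
  expect_error(
    generate_signal_probes(
      signal_spec("low", c(50, 80), c(15, 20), 1),
      n_per_group = 5, seed = 1
    ),
    "cannot fit"
  )
  expect_error(signal_spec("high", c(40, 25), c(6, 8), 5), "diff_range")
  expect_error(signal_spec("high", c(25, 40), c(6, 8), 0), "n_probes")
})

test_that("validation dataset concatenates background and signal with full truth", {
  gen <- generate_validation_dataset(n_background = 200, n_per_group = 5, seed = 9)
  expect_equal(n_probes(gen$dataset), 230)
  expect_equal(nrow(gen$truth), 230)
  expect_equal(sum(gen$truth$tier == "background"), 200)
  expect_equal(anyDuplicated(gen$dataset$probe_id), 0L)
  # bit-identical under the same seed
  again <- generate_validation_dataset(n_background = 200, n_per_group = 5, seed = 9)
  expect_identical(
    methyl_values(gen$dataset),
    methyl_values(again$dataset)
  )
  # signal-only dataset
  pure <- generate_validation_dataset(n_background = 0, n_per_group = 5, seed = 9)
  expect_equal(n_probes(pure$dataset), 30)
})

test_that("sensitivity samples follow the uniform mu +/- A sigma law", {
  spec <- tibble::tibble(
    probe_id = rep(c("a", "b"), each = 2),
    group = rep(c("g1", "g2"), 2),
    mu = c(2, -1, 0, 4),
    sigma = c(0.5, 1, 0.2, 0.3)
  )
  # A = 0: every value equals its group mean exactly
  syn0 <- generate_sensitivity_samples(spec, A = 0, n_per_group = 7, seed = 1)
  m0 <- methyl_values(syn0)
  g0 <- group_labels(syn0)
  expect_identical(unique(m0["a", g0 == "g1"]), 2)
  expect_identical(unique(m0["b", g0 == "g2"]), 4)
  # A = 1, mu = 2, sigma = 0.5: all values within [1.5, 2.5]
  syn1 <- generate_sensitivity_samples(spec, A = 1, n_per_group = 50, seed = 2)
  m1 <- methyl_values(syn1)
  expect_true(all(m1["a", group_labels(syn1) == "g1"] >= 1.5 &
    m1["a", group_labels(syn1) == "g1"] <= 2.5))
  expect_error(generate_sensitivity_samples(spec, A = -1), "non-negative")
})

test_that("sensitivity sample variance matches (A sigma)^2 / 3", {
  spec <- tibble::tibble(probe_id = "a", group = "g1", mu = 2, sigma = 0.5)
  syn <- generate_sensitivity_samples(spec, A = 10, n_per_group = 1e5, seed = 3)
  v <- var(as.numeric(methyl_values(syn)))
  expect_equal(v, (10 * 0.5)^2 / 3, tolerance = 0.02)
})
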