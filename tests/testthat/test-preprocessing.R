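test_that("M-value transform matches closed forms and round-trips", {
  m <- matrix(c(0.5, 0.8, 0.2, 0.5), 2, 2)
  ds <- make_dataset(m, c("a", "b"), scale = "beta")
  mv <- suppressMessages(to_mvalues(ds))
  expect_equal(methyl_scale(mv), "mvalue")
  expect_equal(unname(methyl_values(mv)[1, 1]), 0) # beta 0.5 -> 0
  expect_equal(unname(methyl_values(mv)[2, 1]), 2) # beta 0.8 -> log2(4)
  # percent 20 -> log2(0.25) = -2
  pc <- make_dataset(matrix(c(20, 20, 50, 50), 2, 2), c("a", "b"),
    scale = "percent"
  )
  expect_equal(unname(methyl_values(suppressMessages(to_mvalues(pc)))[1, 1]), -2)
  # inverse logistic round-trip on random finite betas
  withr::with_seed(1, {
    b <- matrix(runif(60, 0.02, 0.98), 6, 10)
  })
  mv2 <- methyl_values(suppressMessages(to_mvalues(
    make_dataset(b, rep(c("a", "b"), each = 5), scale = "beta")
  )))
  back <- 2^mv2 / (1 + 2^mv2)
  expect_equal(unname(back), unname(b), tolerance = 1e-10)
  # already M-values: warning, unchanged
  expect_warning(out <- to_mvalues(mv), "already")
  expect_identical(methyl_values(out), methyl_values(mv))
})

test_that("non-finite rows are dropped, finite matrices untouched", {
  m <- matrix(rnorm(20), 5, 4)
  m[2, 3] <- Inf
  m[4, 1] <- NaN
  ds <- make_dataset(m, rep(c("a", "b"), each = 2))
  out <- suppressMessages(drop_nonfinite(ds))
  expect_equal(n_probes(out), 3)
  expect_false(any(!is.finite(methyl_values(out))))
  clean <- make_dataset(matrix(rnorm(8), 2, 4), rep(c("a", "b"), each = 2))
  expect_identical(
    methyl_values(drop_nonfinite(clean)),
    methyl_values(clean)
  )
  # boundary beta of 1 becomes +Inf and the probe is removed downstream
  bds <- make_dataset(matrix(c(1, 0.5, 0.4, 0.6), 2, 2), c("a", "b"),
    scale = "beta"
  )
  mv <- suppressMessages(to_mvalues(bds))
  expect_equal(n_probes(suppressMessages(drop_nonfinite(mv))), 1)
})

test_that("probe filtering removes SNP, sex-linked and undetected probes", {
  m <- matrix(rnorm(40), 10, 4)
  ds <- make_dataset(m, rep(c("a", "b"), each = 2))
  ann <- tibble::tibble(
    probe_id = ds$probe_id,
    is_snp = c(TRUE, rep(FALSE, 9)),
    chromosome = c("1", "chrX", "X", "Y", rep("2", 6))
  )
  out <- suppressMessages(filter_probes(ds, ann))
  expect_equal(n_probes(out), 6) # 1 SNP + 3 sex-linked removed
  expect_false("p001" %in% out$probe_id)
  # all-clear annotation is the identity
  ann2 <- tibble::tibble(
    probe_id = ds$probe_id, is_snp = FALSE, chromosome = "5"
  )
  expect_equal(n_probes(suppressMessages(filter_probes(ds, ann2))), 10)
  # detection p >= alpha in any sample excludes the probe
  dp <- tibble::tibble(
    probe_id = ds$probe_id,
    s01 = c(0.2, rep(0.001, 9)), s02 = 0.001, s03 = 0.001, s04 = 0.001
  )
  out3 <- suppressMessages(filter_probes(ds, ann2, detection_p = dp))
  expect_equal(n_probes(out3), 9)
})

test_that("BH q-values equal the hand example and the brute-force oracle", {
  expect_equal(
    bh_fdr(c(0.001, 0.01, 0.02, 0.8)),
    c(0.004, 0.02, 0.02 * 4 / 3, 0.8)
  )
  expect_equal(bh_fdr(0.37), 0.37) # single p
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5)) # ties
  withr::with_seed(42, {
    for (len in 1:12) {
      for (rep in 1:8) {
        p <- round(runif(len), 3)
        expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
      }
    }
  })
  # q-values never drop below p and are monotone in sorted order
  withr::with_seed(7, p <- runif(50))
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
})

test_that("the internal BH rejection shortcut matches full adjustment", {
  withr::with_seed(13, {
    for (rep in 1:20) {
      p <- runif(500)^3
      alpha <- sample(c(0.001, 0.01, 0.05), 1)
      fast <- sort(methylsieve:::bh_reject(p, alpha))
      full <- which(bh_fdr(p) <= alpha)
      expect_equal(fast, full)
    }
  })
})

test_that("batch adjustment removes an additive batch shift", {
  withr::with_seed(21, {
    base <- matrix(rnorm(50 * 40, 0, 1), 50, 40)
    shift <- rnorm(50, 0, 2) # per-probe batch offset
    m <- base
    m[, 21:40] <- m[, 21:40] + shift
  })
  ds <- make_dataset(m, rep(c("a", "b"), 20),
    batch = rep(c("b1", "b2"), each = 20)
  )
  adj <- combat_adjust(ds)
  expect_equal(dim(methyl_values(adj)), dim(m))
  expect_identical(adj$probe_id, ds$probe_id)
  pre_gap <- rowMeans(m[, 1:20]) - rowMeans(m[, 21:40])
  post <- methyl_values(adj)
  post_gap <- rowMeans(post[, 1:20]) - rowMeans(post[, 21:40])
  # empirical-Bayes shrinkage leaves a small residual relative to the shift
  expect_lt(max(abs(post_gap)), 0.1 * max(abs(pre_gap)))
})

test_that("batch adjustment edge cases", {
  ds <- make_dataset(matrix(rnorm(40), 10, 4), rep(c("a", "b"), 2),
    batch = rep("only", 4)
  )
  expect_warning(out <- combat_adjust(ds), "one batch")
  expect_identical(methyl_values(out), methyl_values(ds))
  ds2 <- make_dataset(matrix(rnorm(40), 10, 4), rep(c("a", "b"), 2),
    batch = c("b1", "b1", "b1", "b2")
  )
  expect_error(combat_adjust(ds2), "b2")
})
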