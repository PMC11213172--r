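# Small fixture builders and independent oracles used across the suite;
# everything is generated in code under fixed seeds.

make_dataset <- function(values, groups, scale = "mvalue", batch = NULL) {
  n <- ncol(values)
  if (is.null(colnames(values))) colnames(values) <- sprintf("s%02d", seq_len(n))
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("p%03d", seq_len(nrow(values)))
  }
  sheet <- tibble::tibble(sample_id = colnames(values), group = groups)
  if (!is.null(batch)) sheet$batch <- batch
  methyl_dataset(values, sheet, scale = scale)
}

# Two well-separated groups on the M-value scale: `n_signal` informative
# probes with group mean difference `delta`, the rest pure noise.
make_two_group_mvalues <- function(n_probes = 20, n_signal = 4,
                                   n_per_group = 10, delta = 3, sd = 0.5,
                                   seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(stats::rnorm(n_probes * 2 * n_per_group, 0, sd),
      nrow = n_probes
    )
    if (n_signal > 0) {
      m[seq_len(n_signal), seq_len(n_per_group) + n_per_group] <-
        m[seq_len(n_signal), seq_len(n_per_group) + n_per_group] + delta
    }
    make_dataset(m, rep(c("control", "positive"), each = n_per_group))
  })
}

# Four cohorts shaped like the study design (control 8, cp 10, epilepsy 4,
# cp_epilepsy 8): cp-linked signal in the first probes, optionally
# epilepsy-linked signal in the probes after those.
make_four_group_mvalues <- function(n_probes = 12, n_signal = 3,
                                    n_epi_signal = 0, delta = 3, sd = 0.5,
                                    seed = 1) {
  sizes <- c(control = 8, cp = 10, epilepsy = 4, cp_epilepsy = 8)
  groups <- rep(names(sizes), sizes)
  withr::with_seed(seed, {
    m <- matrix(stats::rnorm(n_probes * length(groups), 0, sd), nrow = n_probes)
    cp_cols <- groups %in% c("cp", "cp_epilepsy")
    m[seq_len(n_signal), cp_cols] <- m[seq_len(n_signal), cp_cols] + delta
    if (n_epi_signal > 0) {
      epi_cols <- groups %in% c("epilepsy", "cp_epilepsy")
      rows <- n_signal + seq_len(n_epi_signal)
      m[rows, epi_cols] <- m[rows, epi_cols] + delta
    }
    make_dataset(m, groups)
  })
}

# Two probes with an exact sample correlation r across all samples.
make_correlated_pair <- function(r, n = 40, seed = 2) {
  withr::with_seed(seed, {
    x <- scale(stats::rnorm(n))[, 1]
    e <- stats::rnorm(n)
    e <- scale(stats::residuals(stats::lm(e ~ x)))[, 1]
    y <- r * x + sqrt(1 - r^2) * e
    m <- rbind(p1 = x, p2 = y)
    colnames(m) <- sprintf("s%02d", seq_len(n))
    m
  })
}

# Literal brute-force Benjamini-Hochberg step-up oracle:
# q_i = min over thresholds t in {p_j : p_j >= p_i} of t * m / #{p <= t}.
bh_oracle <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    ts <- p[p >= pi]
    min(1, vapply(ts, function(t) t * m / sum(p <= t), numeric(1)))
  }, numeric(1))
}

# Exhaustive Otsu oracle: maximize between-class variance over all cuts.
otsu_oracle <- function(x) {
  ux <- sort(unique(x))
  cuts <- (ux[-length(ux)] + ux[-1]) / 2
  n <- length(x)
  bv <- vapply(cuts, function(cut) {
    lower <- x[x <= cut]
    upper <- x[x > cut]
    (length(lower) / n) * (length(upper) / n) *
      (mean(lower) - mean(upper))^2
  }, numeric(1))
  cuts[which.max(bv)]
}

# LP oracle for the dip statistic, straight from the definition:
# dip = min over unimodal cdfs U of sup |F_n - U|. For each modal gap m the
# existence of a fit within d is linear feasibility (band at every ECDF
# corner, monotonicity, convexity up to the gap, concavity after it); two
# extra runs allow an atom of U at either extreme point. Solved with
# boot::simplex; small n and distinct values only.
dip_lp_oracle <- function(x) {
  x <- sort(x)
  n <- length(x)
  yl <- (seq_len(n) - 1) / n
  yu <- seq_len(n) / n
  nv <- n + 1 # variables U_1..U_n, d; all >= 0
  solve_mode <- function(convex_upto, concave_from,
                         skip_yl1 = FALSE, skip_yun = FALSE) {
    A1 <- NULL # A1 x <= b1
    b1 <- NULL
    A2 <- NULL # A2 x >= b2
    b2 <- NULL
    row <- function(coefs) {
      r <- numeric(nv)
      for (cf in coefs) r[cf[1]] <- r[cf[1]] + cf[2]
      r
    }
    for (i in seq_len(n)) {
      if (!(skip_yun && i == n)) {
        A1 <- rbind(A1, row(list(c(i, 1), c(nv, -1))))
        b1 <- c(b1, yu[i])
        A2 <- rbind(A2, row(list(c(i, 1), c(nv, 1))))
        b2 <- c(b2, yu[i])
      }
      if (!(skip_yl1 && i == 1)) {
        A1 <- rbind(A1, row(list(c(i, 1), c(nv, -1))))
        b1 <- c(b1, yl[i])
        A2 <- rbind(A2, row(list(c(i, 1), c(nv, 1))))
        b2 <- c(b2, yl[i])
      }
    }
    for (i in seq_len(n - 1)) {
      A1 <- rbind(A1, row(list(c(i, 1), c(i + 1, -1))))
      b1 <- c(b1, 0)
    }
    if (convex_upto >= 3) {
      for (i in seq_len(convex_upto - 2)) {
        dx1 <- x[i + 1] - x[i]
        dx2 <- x[i + 2] - x[i + 1]
        A1 <- rbind(A1, row(list(
          c(i, -dx2), c(i + 1, dx2 + dx1), c(i + 2, -dx1)
        )))
        b1 <- c(b1, 0)
      }
    }
    if (concave_from <= n - 2) {
      for (i in concave_from:(n - 2)) {
        dx1 <- x[i + 1] - x[i]
        dx2 <- x[i + 2] - x[i + 1]
        A1 <- rbind(A1, row(list(
          c(i, dx2), c(i + 1, -(dx2 + dx1)), c(i + 2, dx1)
        )))
        b1 <- c(b1, 0)
      }
    }
    fit <- suppressWarnings(boot::simplex(
      a = c(numeric(n), 1),
      A1 = A1, b1 = b1, A2 = A2, b2 = b2, maxi = FALSE
    ))
    if (fit$solved == 1) fit$value else Inf
  }
  best <- Inf
  for (m in 0:n) best <- min(best, solve_mode(m, m + 1))
  best <- min(best, solve_mode(0, 1, skip_yl1 = TRUE))
  best <- min(best, solve_mode(n, n + 1, skip_yun = TRUE))
  best
}
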