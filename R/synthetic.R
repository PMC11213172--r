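#' Specification of a planted signal tier
#'
#' Describes one tier of differentially methylated probes for the synthetic
#' validation methylome: how many probes to plant, the range the true
#' between-group mean difference is drawn from, and the range the true
#' within-group standard deviation is drawn from (both in percent-methylation
#' points).
#'
#' @param tier One of `"high"`, `"medium"`, `"low"`.
#' @param diff_range Length-2 numeric, bounds of the between-group mean
#'   difference in percent points, inside (0, 100).
#' @param sd_range Length-2 numeric, bounds of the within-group SD in percent
#'   points, inside (0, 100).
#' @param n_probes Positive integer, probes planted at this tier.
#'
#' @return A `signal_spec` list.
#' @export
#' @examples
#' signal_spec("high", c(25, 40), c(6, 8), 5)
signal_spec <- function(tier = c("high", "medium", "low"),
                        diff_range, sd_range, n_probes) {
  tier <- rlang::arg_match(tier)
  check_range <- function(r, what) {
    if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2] ||
      r[1] <= 0 || r[2] >= 100) {
      rlang::abort(sprintf(
        "`%s` must be an increasing pair inside (0, 100).", what
      ))
    }
  }
  check_range(diff_range, "diff_range")
  if (length(sd_range) != 2 || sd_range[1] > sd_range[2] ||
    any(sd_range < 0) || sd_range[2] >= 100) {
    rlang::abort("`sd_range` must be an increasing pair in [0, 100).")
  }
  if (!is.numeric(n_probes) || n_probes < 1 || n_probes != round(n_probes)) {
    rlang::abort("`n_probes` must be a positive integer.")
  }
  structure(
    list(
      tier = tier, diff_range = as.numeric(diff_range),
      sd_range = as.numeric(sd_range), n_probes = as.integer(n_probes)
    ),
    class = "signal_spec"
  )
}

#' Default signal tiers of the synthetic validation methylome
#'
#' Five high-discriminability probes (between-group mean difference 25--40
#' percent points, within-group SD 6--8), ten medium (difference 15--30, SD
#' 8--10) and fifteen low (difference 10--20, SD 10--12).
#'
#' @return A list of three [signal_spec()] objects.
#' @export
default_signal_specs <- function() {
  list(
    signal_spec("high", c(25, 40), c(6, 8), 5),
    signal_spec("medium", c(15, 30), c(8, 10), 10),
    signal_spec("low", c(10, 20), c(10, 12), 15)
  )
}

#' Generate uninformative background probes
#'
#' Every value is drawn i.i.d. uniform on \[0, 100\] percent methylation, so
#' background probes carry no group signal by construction.
#'
#' @param n_probes Number of background probes (default one million).
#' @param n_per_group Samples per group (two groups, `control` and
#'   `positive`).
#' @param seed Integer seed; generation is fully deterministic given the seed.
#'
#' @return A [methyl_dataset()] on the percent scale with balanced
#'   `control`/`positive` groups.
#' @export
generate_background <- function(n_probes = 1e6, n_per_group = 25, seed) {
  if (n_probes < 1) rlang::abort("`n_probes` must be at least 1.")
  if (n_per_group < 2) rlang::abort("`n_per_group` must be at least 2.")
  n_probes <- as.integer(n_probes)
  n_per_group <- as.integer(n_per_group)
  sheet <- validation_sample_sheet(n_per_group)
  m <- withr::with_seed(
    seed,
    matrix(stats::runif(n_probes * 2 * n_per_group, 0, 100),
      nrow = n_probes, ncol = 2L * n_per_group
    )
  )
  dimnames(m) <- list(
    sprintf("bg_%07d", seq_len(n_probes)),
    sheet$sample_id
  )
  tbl <- tibble::as_tibble(as.data.frame(m), .name_repair = "minimal")
  tbl <- tibble::add_column(tbl, probe_id = rownames(m), .before = 1)
  new_methyl_dataset(tbl, sheet, "percent", seed = seed, validate = FALSE)
}

validation_sample_sheet <- function(n_per_group) {
  tibble::tibble(
    sample_id = c(
      sprintf("ctrl_%02d", seq_len(n_per_group)),
      sprintf("pos_%02d", seq_len(n_per_group))
    ),
    group = rep(c("control", "positive"), each = n_per_group)
  )
}

#' Generate planted differentially methylated probes
#'
#' For each probe of each tier, a true mean difference `d` is drawn uniformly
#' from the tier's `diff_range` and a true within-group SD `s` from its
#' `sd_range`. The control-group mean is placed uniformly inside the interval
#' where both group means stay at least `3 s` away from the 0 and 100
#' boundaries, the sign of the difference is randomized, and per-sample values
#' are drawn from a normal law with the group mean and SD `s`, truncated to
#' (0, 100) so that percent values never sit exactly on a boundary (exact 0 or
#' 100 would map to infinite M-values downstream).
#'
#' @param specs A [signal_spec()] or list of them.
#' @param n_per_group Samples per group.
#' @param seed Integer seed.
#'
#' @return A list with `dataset`, a [methyl_dataset()] of the planted probes,
#'   and `truth`, a tibble `probe_id`/`tier`.
#' @export
generate_signal_probes <- function(specs = default_signal_specs(),
                                   n_per_group = 25, seed) {
  if (inherits(specs, "signal_spec")) specs <- list(specs)
  if (n_per_group < 2) rlang::abort("`n_per_group` must be at least 2.")
  n_per_group <- as.integer(n_per_group)
  for (sp in specs) {
    if (100 - 6 * sp$sd_range[2] - sp$diff_range[2] < 0) {
      rlang::abort(sprintf(
        "Tier '%s' cannot fit in [0, 100]: diff %g with 3-SD margins of SD %g.",
        sp$tier, sp$diff_range[2], sp$sd_range[2]
      ))
    }
  }
  sheet <- validation_sample_sheet(n_per_group)
  withr::local_seed(seed)
  rows <- list()
  truth <- list()
  for (sp in specs) {
    for (k in seq_len(sp$n_probes)) {
      d <- stats::runif(1, sp$diff_range[1], sp$diff_range[2])
      s <- stats::runif(1, sp$sd_range[1], sp$sd_range[2])
      dir <- sample(c(-1, 1), 1)
      # control mean uniform over the placements keeping both means in
      # [3s, 100 - 3s]
      lo <- max(3 * s, 3 * s - dir * d)
      hi <- min(100 - 3 * s, 100 - 3 * s - dir * d)
      m_ctrl <- stats::runif(1, lo, hi)
      m_pos <- m_ctrl + dir * d
      vals <- c(
        rtruncnorm01(n_per_group, m_ctrl, s),
        rtruncnorm01(n_per_group, m_pos, s)
      )
      id <- sprintf("sig_%s_%02d", sp$tier, k)
      rows[[id]] <- vals
      truth[[id]] <- sp$tier
    }
  }
  m <- do.call(rbind, rows)
  colnames(m) <- sheet$sample_id
  tbl <- tibble::as_tibble(as.data.frame(m), .name_repair = "minimal")
  tbl <- tibble::add_column(tbl, probe_id = rownames(m), .before = 1)
  list(
    dataset = new_methyl_dataset(tbl, sheet, "percent",
      seed = seed, validate = FALSE
    ),
    truth = tibble::tibble(
      probe_id = names(truth),
      tier = unlist(truth, use.names = FALSE)
    )
  )
}

# Normal(mean, sd) truncated to (0, 100) by inverse-CDF sampling; sd = 0
# degenerates to the mean.
rtruncnorm01 <- function(n, mean, sd) {
  if (sd == 0) {
    return(rep(mean, n))
  }
  lo <- stats::pnorm(0, mean, sd)
  hi <- stats::pnorm(100, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

#' Generate the full synthetic validation methylome
#'
#' Row-concatenates a uniform background with the planted signal tiers. The
#' defaults reproduce the validation study conditions: one million background
#' probes, 25 control and 25 positive samples, and 5/10/15 planted probes at
#' high/medium/low discriminability.
#'
#' @inheritParams generate_signal_probes
#' @param n_background Number of background probes.
#'
#' @return A list with `dataset` (a [methyl_dataset()], percent scale) and
#'   `truth` (tibble `probe_id`/`tier`, where background probes carry tier
#'   `"background"`).
#' @export
generate_validation_dataset <- function(n_background = 1e6, n_per_group = 25,
                                        specs = default_signal_specs(), seed) {
  withr::local_seed(seed)
  sig <- generate_signal_probes(specs, n_per_group,
    seed = sample.int(.Machine$integer.max, 1)
  )
  if (n_background > 0) {
    bg <- generate_background(n_background, n_per_group,
      seed = sample.int(.Machine$integer.max, 1)
    )
    tbl <- dplyr::bind_rows(
      tibble::as_tibble(bg),
      tibble::as_tibble(sig$dataset)
    )
    truth <- dplyr::bind_rows(
      tibble::tibble(probe_id = bg$probe_id, tier = "background"),
      sig$truth
    )
    sheet <- sample_info(bg)
  } else {
    tbl <- tibble::as_tibble(sig$dataset)
    truth <- sig$truth
    sheet <- sample_info(sig$dataset)
  }
  if (anyDuplicated(tbl$probe_id) > 0) {
    rlang::abort("Internal error: duplicate probe IDs in the combined dataset.")
  }
  list(
    dataset = new_methyl_dataset(tbl, sheet, "percent",
      seed = seed, validate = FALSE
    ),
    truth = truth
  )
}

#' Generate synthetic sensitivity-analysis samples
#'
#' Draws, for every probe and group, `n_per_group` values i.i.d. uniform on
#' \[mu - A sigma, mu + A sigma\], where mu and sigma are the supplied
#' per-probe per-group location and scale on the M-value scale and `A` is the
#' dimensionless width multiplier. At `A = 0` every value equals its group
#' mean exactly.
#'
#' @param spec A tibble with columns `probe_id`, `group`, `mu`, `sigma`
#'   (M-value units, `sigma >= 0`), one row per probe-group pair.
#' @param A Non-negative width multiplier.
#' @param n_per_group Samples generated for each group (default 30).
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#'
#' @return A [methyl_dataset()] on the M-value scale.
#' @export
generate_sensitivity_samples <- function(spec, A, n_per_group = 30, seed = NULL) {
  if (!all(c("probe_id", "group", "mu", "sigma") %in% names(spec))) {
    rlang::abort("`spec` needs columns probe_id, group, mu, sigma.")
  }
  if (A < 0) rlang::abort("`A` must be non-negative.")
  if (any(spec$sigma < 0)) rlang::abort("`sigma` must be non-negative.")
  if (n_per_group < 1) rlang::abort("`n_per_group` must be at least 1.")
  if (!is.null(seed)) withr::local_seed(seed)
  groups <- unique(spec$group)
  probes <- unique(spec$probe_id)
  sheet <- tibble::tibble(
    sample_id = unlist(lapply(groups, function(g) {
      sprintf("syn_%s_%02d", g, seq_len(n_per_group))
    })),
    group = rep(groups, each = n_per_group)
  )
  m <- matrix(NA_real_, length(probes), nrow(sheet),
    dimnames = list(probes, sheet$sample_id)
  )
  for (g in groups) {
    sub <- spec[spec$group == g, ]
    idx <- match(sub$probe_id, probes)
    cols <- which(sheet$group == g)
    half <- A * sub$sigma
    draws <- matrix(
      stats::runif(length(idx) * n_per_group, -1, 1),
      length(idx), n_per_group
    )
    m[idx, cols] <- sub$mu + half * draws
  }
  tbl <- tibble::as_tibble(as.data.frame(m), .name_repair = "minimal")
  tbl <- tibble::add_column(tbl, probe_id = rownames(m), .before = 1)
  new_methyl_dataset(tbl, sheet, "mvalue", validate = FALSE)
}

#' Per-probe per-group location and scale estimates
#'
#' Convenience builder for the sensitivity-sample specification: estimates the
#' mean and SD of every probe in every group of a dataset.
#'
#' @param data A [methyl_dataset()].
#' @param probes Optional character vector restricting the probes.
#' @return A tibble `probe_id`, `group`, `mu`, `sigma`.
#' @export
estimate_group_moments <- function(data, probes = NULL) {
  if (!is.null(probes)) data <- subset_probes(data, probes)
  m <- methyl_values(data)
  g <- group_labels(data)
  purrr::map_dfr(unique(g), function(grp) {
    sub <- m[, g == grp, drop = FALSE]
    tibble::tibble(
      probe_id = rownames(m),
      group = grp,
      mu = rowMeans(sub),
      sigma = row_sds(sub)
    )
  })
}

# Row-wise sample standard deviations without forming per-row copies.
row_sds <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  v <- (rowSums(m * m) - n * mu * mu) / (n - 1)
  sqrt(pmax(v, 0))
}
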