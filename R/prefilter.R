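#' Biomarker prefilter configuration
#'
#' Thresholds for the per-probe biomarker screen applied to two-group
#' percent-methylation data before probe selection. Three criteria are
#' evaluated in each group (six tests per probe):
#'
#' 1. the 95% confidence interval of the group spans less than
#'    `ci_span_limit` percent points,
#' 2. the group mean is below `extreme_mean_low` or above
#'    `extreme_mean_high` percent,
#' 3. the group SD is below `sd_limit` percent points.
#'
#' A probe passes when at least `min_criteria_passes` of the six tests hold
#' and the absolute between-group mean difference is at least
#' `min_mean_diff`.
#'
#' @param ci_level Confidence level of criterion 1 (default 0.95).
#' @param ci_span_limit Maximum criterion-1 interval span, percent points.
#' @param extreme_mean_low,extreme_mean_high Criterion-2 mean thresholds.
#' @param sd_limit Criterion-3 SD threshold, percent points.
#' @param min_criteria_passes Minimum number of the six tests that must hold.
#' @param min_mean_diff Minimum absolute between-group mean difference.
#' @param ci_type Reading of criterion 1: `"mean"` (default) takes the
#'   confidence interval of the group mean, span `2 z SD / sqrt(n)`;
#'   `"population"` takes the central 95% spread of the group values, span
#'   `2 z SD`. See the methods vignette for why both are provided.
#' @return A `prefilter_config` list.
#' @export
prefilter_config <- function(ci_level = 0.95, ci_span_limit = 40,
                             extreme_mean_low = 10, extreme_mean_high = 90,
                             sd_limit = 40, min_criteria_passes = 4,
                             min_mean_diff = 10,
                             ci_type = c("mean", "population")) {
  ci_type <- rlang::arg_match(ci_type)
  lims <- c(ci_span_limit, extreme_mean_low, extreme_mean_high, sd_limit)
  if (any(lims <= 0 | lims >= 100)) {
    rlang::abort("All prefilter limits must lie in (0, 100).")
  }
  if (min_criteria_passes < 1 || min_criteria_passes > 6) {
    rlang::abort("`min_criteria_passes` must be between 1 and 6.")
  }
  structure(
    list(
      ci_level = ci_level, ci_span_limit = ci_span_limit,
      extreme_mean_low = extreme_mean_low,
      extreme_mean_high = extreme_mean_high, sd_limit = sd_limit,
      min_criteria_passes = as.integer(min_criteria_passes),
      min_mean_diff = min_mean_diff, ci_type = ci_type
    ),
    class = "prefilter_config"
  )
}

# Criterion-1 interval span for a vector of group SDs.
ci_span <- function(sd, n, config) {
  z <- stats::qnorm(1 - (1 - config$ci_level) / 2)
  if (config$ci_type == "mean") 2 * z * sd / sqrt(n) else 2 * z * sd
}

#' Evaluate the six biomarker criteria for one probe
#'
#' @param control_values,positive_values Numeric percent-methylation values of
#'   the probe in each group (at least 2 per group).
#' @param config A [prefilter_config()].
#' @return Named logical vector of the six tests:
#'   `c1_control`, `c1_positive`, `c2_control`, `c2_positive`,
#'   `c3_control`, `c3_positive`.
#' @export
#' @examples
#' criterion_checks(rep(50, 5), c(94, 95, 96, 95, 94), prefilter_config())
criterion_checks <- function(control_values, positive_values,
                             config = prefilter_config()) {
  if (length(control_values) < 2 || length(positive_values) < 2) {
    rlang::abort("Each group needs at least 2 values.")
  }
  per_group <- function(v) {
    m <- mean(v)
    s <- stats::sd(v)
    c(
      c1 = ci_span(s, length(v), config) < config$ci_span_limit,
      c2 = m < config$extreme_mean_low || m > config$extreme_mean_high,
      c3 = s < config$sd_limit
    )
  }
  ctrl <- per_group(control_values)
  pos <- per_group(positive_values)
  stats::setNames(
    c(ctrl["c1"], pos["c1"], ctrl["c2"], pos["c2"], ctrl["c3"], pos["c3"]),
    c(
      "c1_control", "c1_positive", "c2_control", "c2_positive",
      "c3_control", "c3_positive"
    )
  )
}

#' Screen probes against biomarker assumptions
#'
#' Applies the six-test biomarker screen of [prefilter_config()] to every
#' probe of a two-group percent-scale dataset, fully vectorized. A probe is
#' kept when at least `min_criteria_passes` tests hold and the absolute
#' between-group mean difference reaches `min_mean_diff` percent points.
#'
#' @param data A [methyl_dataset()] on the percent scale with exactly two
#'   groups.
#' @param config A [prefilter_config()].
#' @return The kept [methyl_dataset()], with attribute `"prefilter_report"`
#'   (retrievable via [prefilter_report()]): a tibble with the six criterion
#'   flags, criterion count, mean difference and keep decision per probe.
#' @export
biomarker_prefilter <- function(data, config = prefilter_config()) {
  groups <- unique(sample_info(data)$group)
  if (length(groups) != 2) {
    rlang::abort("The prefilter expects exactly two groups.")
  }
  if (methyl_scale(data) != "percent") {
    rlang::abort("The prefilter operates on percent methylation values.")
  }
  m <- methyl_values(data)
  g <- group_labels(data)
  stats_for <- function(grp) {
    sub <- m[, g == grp, drop = FALSE]
    n <- ncol(sub)
    mu <- rowMeans(sub)
    s <- row_sds(sub)
    list(
      mu = mu, s = s,
      c1 = ci_span(s, n, config) < config$ci_span_limit,
      c2 = mu < config$extreme_mean_low | mu > config$extreme_mean_high,
      c3 = s < config$sd_limit
    )
  }
  a <- stats_for(groups[1])
  b <- stats_for(groups[2])
  n_pass <- a$c1 + b$c1 + a$c2 + b$c2 + a$c3 + b$c3
  mean_diff <- abs(a$mu - b$mu)
  keep <- n_pass >= config$min_criteria_passes &
    mean_diff >= config$min_mean_diff
  report <- tibble::tibble(
    probe_id = data$probe_id,
    c1_control = a$c1, c1_positive = b$c1,
    c2_control = a$c2, c2_positive = b$c2,
    c3_control = a$c3, c3_positive = b$c3,
    n_criteria = as.integer(n_pass),
    mean_diff = mean_diff,
    kept = keep
  )
  message(sprintf(
    "Biomarker prefilter: %d of %d probes kept.", sum(keep), length(keep)
  ))
  out <- data[keep, , drop = FALSE]
  out <- new_methyl_dataset(out, sample_info(data), methyl_scale(data),
    seed = attr(data, "seed"), validate = FALSE
  )
  attr(out, "prefilter_report") <- report
  out
}

#' @rdname biomarker_prefilter
#' @param x A dataset returned by [biomarker_prefilter()].
#' @export
prefilter_report <- function(x) attr(x, "prefilter_report")
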