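#' Convert beta or percent methylation values to M-values
#'
#' Applies the log-odds transform `M = log2(beta / (1 - beta))`, with
#' `beta = value / 100` for percent-scale data. Fully methylated or fully
#' unmethylated probes (beta of exactly 1 or 0) produce infinite M-values;
#' these are kept in the output but counted in a message so that
#' [drop_nonfinite()] can remove them explicitly, mirroring standard array
#' practice.
#'
#' @param data A [methyl_dataset()] on the beta or percent scale.
#' @return A [methyl_dataset()] on the M-value scale.
#' @export
#' @examples
#' m <- matrix(c(0.5, 0.8, 0.2, 0.5), 2, 2,
#'   dimnames = list(c("p1", "p2"), c("s1", "s2"))
#' )
#' sheet <- tibble::tibble(sample_id = c("s1", "s2"), group = c("a", "b"))
#' to_mvalues(methyl_dataset(m, sheet, scale = "beta"))
to_mvalues <- function(data) {
  if (methyl_scale(data) == "mvalue") {
    rlang::warn("Data already on the M-value scale; returning unchanged.")
    return(data)
  }
  m <- methyl_values(data)
  if (methyl_scale(data) == "percent") m <- m / 100
  mv <- log2(m / (1 - m))
  n_bad <- sum(!is.finite(mv))
  if (n_bad > 0) {
    message(sprintf(
      "%d non-finite M-value(s) produced; remove them with drop_nonfinite().",
      n_bad
    ))
  }
  set_values(data, mv, scale = "mvalue")
}

#' Remove probes with non-finite values
#'
#' Drops every probe row containing an infinite or undefined value. In the
#' standard pipeline this runs on M-values both before and after batch
#' adjustment, removing fully (un)methylated probes whose log-odds are
#' infinite.
#'
#' @param data A [methyl_dataset()].
#' @return The row-subset [methyl_dataset()]; the number of probes removed is
#'   reported in a message when non-zero.
#' @export
drop_nonfinite <- function(data) {
  m <- methyl_values(data)
  ok <- rowSums(!is.finite(m)) == 0
  if (!all(ok)) {
    message(sprintf(
      "Removed %d probe(s) with non-finite values; %d retained.",
      sum(!ok), sum(ok)
    ))
  }
  out <- data[ok, , drop = FALSE]
  new_methyl_dataset(out, sample_info(data), methyl_scale(data),
    seed = attr(data, "seed"), validate = FALSE
  )
}

#' Exclude SNP-overlapping, sex-linked and poorly detected probes
#'
#' Removes probes flagged as common SNPs, probes on the X or Y chromosome,
#' and (when detection p-values are supplied) probes that fail Illumina-style
#' detection in any sample at `detect_alpha`. Probes with no annotation row
#' are kept with a warning.
#'
#' @param data A [methyl_dataset()].
#' @param annotation Tibble with columns `probe_id`, `is_snp` (logical) and
#'   `chromosome` (character, e.g. `"chr1"`, `"chrX"`, `"X"`).
#' @param detection_p Optional tibble of detection p-values: `probe_id` plus
#'   one column per sample, values in \[0, 1\].
#' @param detect_alpha Detection significance level; a probe is excluded if
#'   its detection p-value is `>= detect_alpha` in any sample.
#' @return The filtered [methyl_dataset()] with an attribute
#'   `"filter_report"`, a tibble of probes removed per rule.
#' @export
filter_probes <- function(data, annotation, detection_p = NULL,
                          detect_alpha = 0.05) {
  if (!all(c("probe_id", "is_snp", "chromosome") %in% names(annotation))) {
    rlang::abort("`annotation` needs columns probe_id, is_snp, chromosome.")
  }
  idx <- match(data$probe_id, annotation$probe_id)
  if (anyNA(idx)) {
    rlang::warn(sprintf(
      "%d probe(s) have no annotation row and are kept.", sum(is.na(idx))
    ))
  }
  is_snp <- !is.na(idx) & annotation$is_snp[idx] %in% TRUE
  chrom <- sub("^chr", "", as.character(annotation$chromosome[idx]))
  is_sex <- !is.na(idx) & chrom %in% c("X", "Y")
  fails_detection <- rep(FALSE, n_probes(data))
  if (!is.null(detection_p)) {
    dp <- detection_p[match(data$probe_id, detection_p$probe_id), , drop = FALSE]
    dm <- as.matrix(dp[, setdiff(names(dp), "probe_id"), drop = FALSE])
    if (any(dm < 0 | dm > 1, na.rm = TRUE)) {
      rlang::abort("Detection p-values must lie in [0, 1].")
    }
    fails_detection <- rowSums(dm >= detect_alpha, na.rm = TRUE) > 0
  }
  drop <- is_snp | is_sex | fails_detection
  report <- tibble::tibble(
    rule = c("snp", "sex_chromosome", "detection", "retained"),
    n_probes = c(
      sum(is_snp), sum(is_sex & !is_snp),
      sum(fails_detection & !is_snp & !is_sex), sum(!drop)
    )
  )
  message(paste(
    sprintf("%s: %d", report$rule, report$n_probes),
    collapse = ", "
  ))
  out <- data[!drop, , drop = FALSE]
  out <- new_methyl_dataset(out, sample_info(data), methyl_scale(data),
    seed = attr(data, "seed"), validate = FALSE
  )
  attr(out, "filter_report") <- report
  out
}

#' Empirical-Bayes batch adjustment of M-values
#'
#' Removes additive and multiplicative batch effects with the parametric
#' empirical-Bayes location/scale model (ComBat): each probe is standardized,
#' per-batch location and scale estimates are shrunk toward batch-level
#' priors, and the fitted batch effects are subtracted and rescaled. Group
#' structure is preserved by including the group labels as model covariates.
#'
#' @param data A [methyl_dataset()] on the M-value scale whose sample sheet
#'   has a `batch` column.
#' @param preserve_groups Include group labels as covariates so that
#'   biological differences are not absorbed into batch estimates (default
#'   `TRUE`).
#' @return A batch-adjusted [methyl_dataset()] of the same shape and scale.
#' @export
combat_adjust <- function(data, preserve_groups = TRUE) {
  samples <- sample_info(data)
  if (!"batch" %in% names(samples)) {
    rlang::abort("The sample sheet has no `batch` column.")
  }
  if (methyl_scale(data) != "mvalue") {
    rlang::abort("Batch adjustment expects M-values; run to_mvalues() first.")
  }
  cols <- setdiff(names(data), "probe_id")
  batch <- samples$batch[match(cols, samples$sample_id)]
  sizes <- table(batch)
  if (length(sizes) < 2) {
    rlang::warn("Only one batch present; returning data unchanged.")
    return(data)
  }
  if (any(sizes < 2)) {
    rlang::abort(sprintf(
      "Batch(es) with fewer than 2 samples: %s.",
      paste(names(sizes)[sizes < 2], collapse = ", ")
    ))
  }
  mod <- NULL
  if (preserve_groups && length(unique(samples$group)) > 1) {
    grp <- factor(samples$group[match(cols, samples$sample_id)])
    mod <- stats::model.matrix(~grp)
  }
  m <- methyl_values(data)
  adj <- sva::ComBat(dat = m, batch = batch, mod = mod, par.prior = TRUE)
  set_values(data, adj)
}

#' Benjamini-Hochberg false-discovery-rate q-values
#'
#' Step-up adjusted p-values in the input order:
#' `q_i = min over j with p_(j) >= p_(i) of p_(j) * m / rank(j)`, capped at 1.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order.
#' @export
#' @examples
#' bh_fdr(c(0.001, 0.01, 0.02, 0.8))
bh_fdr <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    rlang::abort("All p-values must lie in [0, 1].")
  }
  stats::p.adjust(pvalues, method = "BH")
}

# Exact BH rejection set at level alpha without adjusting every p-value:
# reject the k smallest p-values where k is the largest rank with
# p_(k) <= alpha * k / m. Candidates can only have p <= alpha, so the sort
# runs over that (usually tiny) subset.
bh_reject <- function(pvalues, alpha) {
  m <- length(pvalues)
  small <- which(pvalues <= alpha)
  if (length(small) == 0) {
    return(integer(0))
  }
  ord <- small[order(pvalues[small])]
  ps <- pvalues[ord]
  ok <- ps <= alpha * seq_along(ps) / m
  if (!any(ok)) {
    return(integer(0))
  }
  ord[seq_len(max(which(ok)))]
}
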