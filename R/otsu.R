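#' Exact one-dimensional Otsu threshold
#'
#' Finds the cut maximizing the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2` over all candidate thresholds placed at
#' midpoints of consecutive distinct sorted values — an exact search on the
#' raw continuous values, with no histogram binning. Ties between maximizing
#' thresholds are broken toward the smallest threshold, which keeps the
#' larger upper class.
#'
#' @param scores Numeric vector with at least 2 distinct values.
#' @return A list with `threshold` (the cut value), `in_upper` (logical,
#'   `scores > threshold` in input order) and `between_variance` at the
#'   optimum.
#' @export
#' @examples
#' otsu_threshold(c(0, 0, 0, 10, 10, 10))$threshold
otsu_threshold <- function(scores) {
  scores <- as.numeric(scores)
  if (anyNA(scores)) rlang::abort("`scores` must not contain missing values.")
  ux <- sort(unique(scores))
  if (length(ux) < 2) {
    rlang::abort("Otsu thresholding needs at least 2 distinct values.")
  }
  s <- sort(scores)
  n <- length(s)
  cuts <- (ux[-length(ux)] + ux[-1]) / 2
  # class sizes and sums below each cut, via cumulative sums over the sorted
  # sample evaluated at the last index <= cut
  idx <- findInterval(cuts, s)
  csum <- cumsum(s)
  n0 <- idx
  n1 <- n - n0
  m0 <- csum[idx] / n0
  m1 <- (csum[n] - csum[idx]) / n1
  bv <- (n0 / n) * (n1 / n) * (m0 - m1)^2
  best <- which.max(bv) # first maximum = smallest threshold
  list(
    threshold = cuts[best],
    in_upper = scores > cuts[best],
    between_variance = bv[best]
  )
}
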