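#' Hartigan-Hartigan dip statistic
#'
#' The dip of a sample is the smallest sup-norm distance between its
#' empirical distribution function and any unimodal distribution function
#' (convex below its mode, concave above it, with an atom permitted at the
#' mode). It is computed exactly, by bisection on the corridor half-width
#' `d`: a unimodal fit within distance `d` exists precisely when a
#' nondecreasing convex-then-concave path threads the corridor
#' `[F_n - d, F_n + d]`, and threading feasibility is decided by propagating
#' the exact reachable frontier of (value, entering-slope) pairs through the
#' corridor, forward for the convex limb and backward (by reflection) for the
#' concave limb, over every candidate modal position. Every sample of size
#' `n` satisfies `dip >= 1/(2n)`, with equality when the ECDF is itself
#' compatible with a unimodal law.
#'
#' @param x Numeric vector.
#' @return The dip statistic, a single non-negative number.
#' @export
#' @examples
#' dip_stat(c(stats::rnorm(50, -3), stats::rnorm(50, 3))) # clearly bimodal
dip_stat <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 0 || anyNA(x)) {
    rlang::abort("`x` must be non-empty and free of missing values.")
  }
  .dip_stat_cpp(x)
}

#' Dip test for multimodality with Monte-Carlo calibration
#'
#' Computes the dip statistic of `x` and calibrates its p-value against
#' `n_null` uniform samples of the same size, the recommended reference
#' distribution for the unimodal null. Small p-values indicate departure from
#' unimodality (bi- or multimodality).
#'
#' @param x Numeric vector with at least 4 distinct values.
#' @param n_null Number of Monte-Carlo null samples (default 2000).
#' @param seed Optional integer seed for the null draws; when `NULL` the
#'   current RNG stream is used.
#' @return A list with `statistic` (the dip), `p_value`
#'   (`(1 + #\{null >= dip\}) / (n_null + 1)`), `n` and `n_null`.
#' @export
#' @examples
#' dip_test(stats::runif(100), n_null = 200, seed = 1)$p_value # unimodal
dip_test <- function(x, n_null = 2000, seed = NULL) {
  if (length(unique(x)) < 4) {
    rlang::abort("The dip test needs at least 4 distinct values.")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  n <- length(x)
  observed <- dip_stat(x)
  null_dips <- vapply(
    seq_len(n_null),
    function(i) .dip_stat_cpp(stats::runif(n)),
    numeric(1)
  )
  list(
    statistic = observed,
    p_value = (1 + sum(null_dips >= observed)) / (n_null + 1),
    n = n,
    n_null = n_null
  )
}
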