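#' Fit a classifier on methylation features
#'
#' Wraps the two classifier families used throughout the pipeline: a
#' soft-margin SVM (radial or linear kernel) and pooled-covariance
#' maximum-likelihood LDA. The radial kernel width defaults to
#' `1 / (n_features * mean feature variance)`, the common variance-scaled
#' choice; features are not rescaled internally so the kernel width retains
#' its M-value interpretation.
#'
#' @param x Numeric matrix, samples in rows and features (probes) in columns.
#' @param y Class labels, one per row of `x` (at least two classes).
#' @param kind One of `"svm_rbf"`, `"svm_linear"`, `"lda"`.
#' @param cost SVM regularization constant `C` (default 1).
#' @return A `methyl_classifier` object with a [predict()] method returning a
#'   factor of class labels.
#' @export
#' @examples
#' x <- matrix(c(rnorm(10, -2), rnorm(10, 2)), ncol = 1)
#' y <- rep(c("a", "b"), each = 10)
#' fit <- fit_classifier(x, y, kind = "lda")
#' predict(fit, x)
fit_classifier <- function(x, y, kind = c("svm_rbf", "svm_linear", "lda"),
                           cost = 1) {
  kind <- rlang::arg_match(kind)
  if (cost <= 0) rlang::abort("`cost` must be positive.")
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) < 2) {
    rlang::abort("Training labels contain a single class.")
  }
  if (length(y) != nrow(x)) {
    rlang::abort("`x` and `y` disagree on the number of samples.")
  }
  if (nrow(x) < nlevels(y)) {
    rlang::abort("Need at least as many samples as classes.")
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  fit <- switch(kind,
    svm_rbf = e1071::svm(
      x = x, y = y, kernel = "radial", cost = cost,
      gamma = 1 / (ncol(x) * max(mean(apply(x, 2, stats::var)), 1e-12)),
      scale = FALSE
    ),
    svm_linear = e1071::svm(
      x = x, y = y, kernel = "linear", cost = cost, scale = FALSE
    ),
    lda = MASS::lda(x = x, grouping = y)
  )
  structure(
    list(kind = kind, fit = fit, features = colnames(x), levels = levels(y)),
    class = "methyl_classifier"
  )
}

#' @export
predict.methyl_classifier <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0) {
    return(factor(character(0), levels = object$levels))
  }
  if (!is.null(object$features)) {
    if (!is.null(colnames(newdata))) {
      if (!all(object$features %in% colnames(newdata))) {
        rlang::abort("`newdata` is missing training features.")
      }
      newdata <- newdata[, object$features, drop = FALSE]
    } else if (ncol(newdata) != length(object$features)) {
      rlang::abort("`newdata` feature count differs from training.")
    }
  }
  if (object$kind == "lda") {
    stats::predict(object$fit, newdata)$class
  } else {
    stats::predict(object$fit, newdata)
  }
}

#' @export
print.methyl_classifier <- function(x, ...) {
  cat(sprintf(
    "<methyl_classifier> %s on %d feature(s), classes: %s\n",
    x$kind, length(x$features), paste(x$levels, collapse = ", ")
  ))
  invisible(x)
}

#' Support-weighted one-vs-rest F1 score
#'
#' For every class, precision and recall of the class-vs-rest dichotomy are
#' combined into an F1 score (0 when precision and recall are both 0); class
#' scores are averaged weighted by class support. The score lies in \[0, 1\],
#' equals 1 exactly for perfect prediction, and is roughly 0.5 for a random
#' predictor on balanced binary labels.
#'
#' @param truth Vector of true class labels.
#' @param estimate Vector of predicted labels, same length.
#' @return A single number in \[0, 1\].
#' @export
#' @examples
#' weighted_ovr_f1(c("P", "P", "N", "N"), c("P", "N", "N", "N"))
weighted_ovr_f1 <- function(truth, estimate) {
  if (length(truth) != length(estimate)) {
    rlang::abort("`truth` and `estimate` must have the same length.")
  }
  if (length(truth) == 0) rlang::abort("Need at least one sample.")
  truth <- as.character(truth)
  estimate <- as.character(estimate)
  n <- length(truth)
  total <- 0
  for (cls in unique(truth)) {
    tp <- sum(truth == cls & estimate == cls)
    fp <- sum(truth != cls & estimate == cls)
    fn <- sum(truth == cls & estimate != cls)
    f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    total <- total + (sum(truth == cls) / n) * f1
  }
  total
}
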