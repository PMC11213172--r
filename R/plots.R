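#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the bootstrap score distribution of a selection round
#'
#' Histogram of per-probe mean scores on a log10-count axis (the background
#' mass at zero dwarfs the signal otherwise), with the round's Otsu
#' threshold as a dashed line.
#'
#' @param object A `methyl_selection` from [select_probes()].
#' @param round Which round to plot (default 1).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot methyl_selection
#' @export
autoplot.methyl_selection <- function(object, round = 1, ...) {
  r <- object$rounds[[round]]
  ggplot2::ggplot(r$score_table, ggplot2::aes(x = .data$mean_score)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey35") +
    ggplot2::geom_vline(
      xintercept = r$otsu_threshold,
      linetype = "dashed", colour = "firebrick"
    ) +
    ggplot2::labs(
      x = "mean bootstrap score", y = "probes",
      title = sprintf(
        "Selection round %d (dip p = %.3g)", round, r$dip_p
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a sensitivity curve
#'
#' Median weighted one-vs-rest F1 against the uniform-noise width multiplier
#' A, with the interquartile band over replicate synthetic draws and the 0.5
#' random-performance reference line.
#'
#' @param object A `methyl_sensitivity` from [sensitivity_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot methyl_sensitivity
#' @export
autoplot.methyl_sensitivity <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$A, y = .data$median_f1)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
      fill = "steelblue", alpha = 0.25
    ) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0.5, colour = "firebrick") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "standard deviations from the group mean (A)",
      y = "median weighted one-vs-rest F1",
      title = sprintf("Sensitivity, %s", attr(object, "model"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot PCA scores with a held-out group highlighted
#'
#' @param object A `methyl_pca` from [pca_project_heldout()].
#' @param components Which two components to display (default `c(1, 2)`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot methyl_pca
#' @export
autoplot.methyl_pca <- function(object, components = c(1, 2), ...) {
  ev <- attr(object, "explained_variance")
  xc <- paste0("PC", components[1])
  yc <- paste0("PC", components[2])
  ggplot2::ggplot(
    object,
    ggplot2::aes(
      x = .data[[xc]], y = .data[[yc]],
      colour = .data$group, shape = .data$heldout
    )
  ) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_shape_manual(
      values = c(`FALSE` = 16, `TRUE` = 4),
      labels = c("fitted", "projected"), name = NULL
    ) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", xc, 100 * ev[components[1]]),
      y = sprintf("%s (%.1f%%)", yc, 100 * ev[components[2]])
    ) +
    ggplot2::theme_minimal()
}

#' Plot the F1 distribution of a performance bootstrap
#'
#' @param object A `methyl_performance` from [performance_bootstrap()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot methyl_performance
#' @export
autoplot.methyl_performance <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$f1)) +
    ggplot2::geom_histogram(
      binwidth = 0.05, boundary = 0,
      fill = "grey35"
    ) +
    ggplot2::geom_vline(
      xintercept = object$median_f1,
      colour = "firebrick", linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "weighted one-vs-rest F1", y = "iterations",
      title = sprintf(
        "%s (%s): median F1 = %.3f", object$model,
        object$comparison, object$median_f1
      )
    ) +
    ggplot2::theme_minimal()
}
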