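#' Plot a cutoff calibration curve
#'
#' Positive predictive value and number of called sites as a function of the
#' per-allele pooled read-depth cutoff.
#'
#' @param calibration A `scase_calibration` from [calibrate_cutoff()].
#' @return A ggplot object.
#' @export
plot_calibration <- function(calibration) {
  x <- tidyr::pivot_longer(
    calibration[, c("cutoff", "ppv", "tpr")], -"cutoff",
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(x, ggplot2::aes(x = .data$cutoff, y = .data$value,
                                  colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "per-allele pooled depth cutoff", y = NULL,
                  colour = NULL,
                  title = "hetSNP calling calibration") +
    ggplot2::theme_minimal()
}

#' Histogram of pooled reference-allele ratios
#'
#' @param pseudo_bulk Output of [pseudo_bulk_ratios()].
#' @param binwidth Bin width (default 0.1).
#' @return A ggplot object, faceted by group when a cell-type column is
#'   present.
#' @export
plot_ratio_histogram <- function(pseudo_bulk, binwidth = 0.1) {
  p <- ggplot2::ggplot(pseudo_bulk, ggplot2::aes(x = .data$ref_ratio)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "pooled reference allele ratio", y = "hetSNP sites") +
    ggplot2::theme_minimal()
  if ("cell_type" %in% names(pseudo_bulk)) {
    p <- p + ggplot2::facet_grid(individual ~ cell_type)
  } else if ("individual" %in% names(pseudo_bulk)) {
    p <- p + ggplot2::facet_wrap(~individual)
  }
  p
}

#' Plot within- versus between-type overlap distributions
#'
#' @param object A `scase_ma_permutation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scase_ma_permutation <- function(object, ...) {
  x <- tidy(object)
  ggplot2::ggplot(x, ggplot2::aes(x = .data$overlap, fill = .data$comparison)) +
    ggplot2::geom_histogram(position = "identity", alpha = 0.6, bins = 30) +
    ggplot2::labs(x = "overlapping cell-type MA genes", y = "iterations",
                  fill = NULL,
                  title = sprintf("%s within vs %s between (k = %d)",
                                  object$type_a, object$type_b, object$k)) +
    ggplot2::theme_minimal()
}

#' Plot a saturation curve
#'
#' @param saturation Output of [saturation_curve()].
#' @return A ggplot object.
#' @export
plot_saturation <- function(saturation) {
  ggplot2::ggplot(saturation, ggplot2::aes(x = .data$k, y = .data$mean_n_ma)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "cells subsampled", y = "mean cell-type MA genes") +
    ggplot2::theme_minimal()
}
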