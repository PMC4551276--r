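#' Plot an ROC curve
#'
#' @param object A `roc_curve` tibble from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot: the trapezoidal ROC polyline with the chance diagonal.
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$far, y = .data$tar)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "False accept rate", y = "True accept rate") +
    ggplot2::theme_minimal()
}

#' Plot the two discretized score distributions
#'
#' @param object A `score_distribution` from [score_distribution()].
#' @param ... Unused.
#' @return A ggplot of the per-class probability mass over the support.
#' @export
autoplot.score_distribution <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("score", "p_genuine", "p_impostor")],
    cols = c("p_genuine", "p_impostor"),
    names_to = "class", values_to = "probability",
    names_prefix = "p_")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$score, y = .data$probability,
                                     fill = .data$class)) +
    ggplot2::geom_col(position = "identity", alpha = 0.55, width = NULL) +
    ggplot2::labs(x = "Score", y = "Probability", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot bootstrap-variability calibration curves
#'
#' Coefficients of variation of the bootstrap SE and of the CI bounds
#' against the number of replications, on a log CV scale (the bound CVs are
#' typically orders of magnitude below the SE CV when the bounds sit near
#' 1).
#'
#' @param object A `roc_variability` from [bootstrap_variability()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roc_variability <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = c("cv_se", "cv_lb", "cv_ub"),
                              names_to = "quantity", values_to = "cv")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$B, y = .data$cv,
                                     colour = .data$quantity,
                                     linetype = .data$statistic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Bootstrap replications B",
                  y = "Coefficient of variation") +
    ggplot2::theme_minimal()
}

#' Histogram of bootstrap replications
#'
#' @param object A `roc_boot` from [roc_bootstrap()].
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot, faceted by statistic component, with the point
#'   estimate marked.
#' @export
autoplot.roc_boot <- function(object, bins = 40, ...) {
  pts <- tibble::tibble(statistic = names(object$point_estimate),
                        value = unname(object$point_estimate))
  ggplot2::ggplot(object$replications, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(data = pts, ggplot2::aes(xintercept = .data$value),
                        colour = "red") +
    ggplot2::facet_wrap(~statistic, scales = "free") +
    ggplot2::labs(x = "Bootstrap replication value", y = "Count") +
    ggplot2::theme_minimal()
}
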