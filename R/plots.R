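#' Scatter of outcome against exposure associations for one MR fit
#'
#' Each point is one instrument (`b_xz`, `b_yz`); the line through the origin
#' has slope equal to the causal estimate, so pleiotropic outliers stand off
#' the line.
#'
#' @param object An `mr_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mr_result <- function(object, ...) {
  e <- object$estimate
  ggplot2::ggplot(object$snps, ggplot2::aes(x = .data$b_xz, y = .data$b_yz)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_abline(intercept = 0, slope = e$beta, colour = "#b2182b") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "instrument-exposure association",
      y = "instrument-outcome association",
      title = sprintf("%s: beta = %.3g (se %.3g), p = %.3g", e$method,
                      e$beta, e$se, e$pvalue)) +
    ggplot2::theme_minimal()
}

#' Calibration plot for a refined-coefficient study
#'
#' Estimated coefficients against the true direct effects, one panel per
#' estimator, with the identity line; refined coefficients should hug the
#' identity while single-locus coefficients drift off it as LD grows.
#'
#' @param object A `refine_sim` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.refine_sim <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("single_locus", "refined_external", "refined_internal",
             "multivariable"),
    names_to = "estimator", values_to = "estimate")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$truth, y = .data$estimate)) +
    ggplot2::geom_abline(colour = "grey50", linetype = 2) +
    ggplot2::geom_point(alpha = 0.15, size = 0.4) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "#b2182b", linewidth = 0.6) +
    ggplot2::facet_wrap(~estimator) +
    ggplot2::labs(x = "true direct effect", y = "estimated coefficient") +
    ggplot2::theme_minimal()
}

#' Bar chart of per-method operating characteristics
#'
#' Rejection rate (type I error under the null, power under the
#' alternative), bias and MSE per estimator from one simulation scenario.
#'
#' @param object An `mr_sim` tibble from [simulate_mr_study()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mr_sim <- function(object, ...) {
  cfg <- attr(object, "config")
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("rejection_rate", "bias", "mse"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$method, y = .data$value)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf(
                    "J = %d, rho = %.1f, b_xy = %.2g, %d replicates",
                    cfg$J, cfg$rho, cfg$b_xy, cfg$n_reps)) +
    ggplot2::theme_minimal()
}
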