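# ggplot2 display methods for the fitted objects.

#' Plot a fitted dilution curve with its critical points
#'
#' @param object A `cndc_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cndc_fit <- function(object, ...) {
  pts <- object$critical_points
  rng <- range(pts$dw)
  curve_dat <- tibble(dw = seq(max(rng[1] * 0.8, 1e-3), rng[2] * 1.1,
                               length.out = 200)) %>%
    mutate(nc = predict_nc(object$curve, .data$dw))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$dw, y = .data$nc)) +
    ggplot2::geom_line(data = curve_dat, colour = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "Dry matter (t/ha)", y = "Critical N concentration (g/kg)",
      title = sprintf("Nc = %.3f DW^-%.3f (%s)", object$curve$a_c,
                      object$curve$b, object$part),
      subtitle = sprintf("R2 = %.3f over %d stage critical points",
                         object$curve$r2, object$curve$n_points)) +
    ggplot2::theme_minimal()
}

#' 1:1 plot of predicted vs observed concentrations
#'
#' @param object A `validation_report` carrying its `pairs` tibble (from
#'   [validate_cndc()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.validation_report <- function(object, ...) {
  if (is.null(object$pairs)) {
    abort("this validation report carries no paired data to plot",
          class = "cndc_domain_error")
  }
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Observed N concentration (g/kg)",
                  y = "Predicted N concentration (g/kg)",
                  title = sprintf("RMSE %.2f g/kg | nRMSE %.2f%% (%s)",
                                  object$rmse, object$nrmse, object$rating)) +
    ggplot2::theme_minimal()
}

#' Plot a linear-plateau fit
#'
#' @param object A `linear_plateau_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.linear_plateau_fit <- function(object, ...) {
  line_dat <- tibble(x = seq(min(object$data$x), max(object$data$x),
                             length.out = 200)) %>%
    mutate(y = predict_linear_plateau(object, .data$x))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line(data = line_dat, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$breakpoint, linetype = 3) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "NNI", y = "Relative yield",
                  title = sprintf("y = %.4f x %+.4f up to x = %.3f; plateau %.3f",
                                  object$slope, object$intercept,
                                  object$breakpoint, object$plateau)) +
    ggplot2::theme_minimal()
}

#' NNI trajectories by treatment across stages
#'
#' @param nni Tibble of NNI records from [diagnose_nni()].
#' @return A ggplot of NNI vs stage, one line per treatment, faceted by
#'   year, with the adequacy line at 1.
#' @export
plot_nni <- function(nni) {
  ggplot2::ggplot(nni, ggplot2::aes(x = .data$stage, y = .data$nni,
                                    colour = .data$treatment,
                                    group = .data$treatment)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~year) +
    ggplot2::labs(x = NULL, y = "Nitrogen nutrition index") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
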