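# Figure-style plots. Plots are optional artifacts; no computation
# depends on them.

#' Plot simulated response rates and the fitted curve
#'
#' Response rate against mean dose (log rate axis), the fitted
#' cumulative-lognormal curve as a solid line and, when the threshold
#' distribution is known, the no-dispersion (`sigma1 = 0`) curve dashed.
#'
#' @param sweep A [run_sweep()] result.
#' @param fit A converged cumulative-lognormal `dose_response_fit`.
#' @param threshold Optional [lognormal_params()]; defaults to the sweep's
#'   config when available.
#' @return A ggplot object.
#' @export
plot_sweep_fit <- function(sweep, fit, threshold = NULL) {
  stopifnot(inherits(fit, "dose_response_fit"))
  df <- as.data.frame(sweep)
  if (is.null(threshold) && !is.null(attr(sweep, "config")))
    threshold <- attr(sweep, "config")$threshold
  grid <- data.frame(mean_dose = exp(seq(log(min(df$mean_dose)),
                                         log(max(df$mean_dose)),
                                         length.out = 200)))
  curve <- lognormal_params(fit$estimates[["mu"]], fit$estimates[["sigma"]])
  grid$fitted <- lognormal_cdf(grid$mean_dose, curve)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = mean_dose, y = rate)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(y = fitted), colour = "blue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Mean dose (mSv)", y = "Response rate",
                  title = "Simulated response rates and cumulative-lognormal fit")
  if (!is.null(threshold)) {
    grid$nodisp <- lognormal_cdf(grid$mean_dose,
                                 as_lognormal_params(threshold))
    p <- p + ggplot2::geom_line(data = grid,
                                ggplot2::aes(y = nodisp),
                                linetype = "dashed")
  }
  p
}

#' Plot observed/reduced-model rate ratios against lagged burden
#'
#' One point per period with one-standard-deviation error bars, the fitted
#' excess curve `1 + A * Lambda(burden)`, and optionally a vertical line at
#' the practical threshold.
#'
#' @param ratios A [rate_ratio_curve()] result.
#' @param fit The `epi_fit` behind it (draws the fitted curve).
#' @param threshold Optional burden (Bq/kg) to annotate, e.g. a
#'   [practical_threshold()] value.
#' @return A ggplot object.
#' @export
plot_rate_ratios <- function(ratios, fit = NULL, threshold = NULL) {
  p <- ggplot2::ggplot(ratios, ggplot2::aes(x = burden, y = ratio)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = ratio - sd,
                                        ymax = ratio + sd),
                           width = 0, colour = "grey50", na.rm = TRUE) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::labs(x = "Cesium burden (Bq/kg), lagged",
                  y = "Observed / predicted rate ratio")
  if (!is.null(fit)) {
    grid <- data.frame(burden = seq(0, max(ratios$burden), length.out = 200))
    grid$ratio <- 1 + fit$amplitude *
      lognormal_cdf_safe(grid$burden, fit$mu, fit$sigma)
    p <- p + ggplot2::geom_line(data = grid, colour = "blue")
  }
  if (!is.null(threshold) && is.finite(threshold))
    p <- p + ggplot2::geom_vline(xintercept = as.numeric(threshold),
                                 linetype = "dashed")
  p
}
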