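# Iteratively reweighted nonlinear least squares for dose-response curves.
#
# Both mean functions (cumulative lognormal and power law) are fitted by
# the same scheme: weighted nonlinear least squares with binomial weights
# w_i = N_i / (p_i (1 - p_i)) recomputed from the *fitted* rates after each
# outer iteration, until the parameters stabilise. Weights from fitted
# (never observed) rates keep zero-event points usable. At rates below
# ~1e-2 this is numerically indistinguishable from Poisson weights N/p.

RATE_EPS <- 1e-12

as_sweep_points <- function(points) {
  points <- as.data.frame(points)
  need <- c("mean_dose", "rate", "trials")
  if (!all(need %in% names(points)))
    stop("points must have columns mean_dose, rate, trials")
  if (any(points$mean_dose <= 0)) stop("mean_dose must be positive")
  if (any(points$rate < 0 | points$rate > 1)) stop("rates must lie in [0, 1]")
  points
}

clamp_rate <- function(p) pmin(pmax(p, RATE_EPS), 1 - RATE_EPS)

binomial_weights <- function(fitted, trials) {
  p <- clamp_rate(fitted)
  trials / (p * (1 - p))
}

new_fit_result <- function(model, estimates, std_errors, deviance, df,
                           converged, n_iterations, fitted_rates, points) {
  structure(list(model = model, estimates = estimates,
                 std_errors = std_errors, deviance = deviance, df = df,
                 converged = converged, n_iterations = n_iterations,
                 fitted_rates = fitted_rates, data = points),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s, %d iterations)\n", x$model,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  est <- rbind(estimate = x$estimates, SE = x$std_errors)
  print(round(est, 4))
  cat(sprintf("Deviance: %.3g on %d df\n", x$deviance, x$df))
  invisible(x)
}

irls_loop <- function(points, mean_fun, start, max_iter, tol) {
  # mean_fun: function(params named list/vector, x) -> fitted rates
  # returns list(nls_fit, params, n_iter, converged)
  x <- points$mean_dose
  y <- points$rate
  params <- start
  form <- attr(mean_fun, "formula")
  fit <- NULL
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    w <- binomial_weights(mean_fun(params, x), points$trials)
    d <- data.frame(x = x, y = y, w = w)
    fit <- minpack.lm::nlsLM(form, data = d, start = as.list(params),
                             weights = w,
                             control = minpack.lm::nls.lm.control(
                               maxiter = 200, ftol = 1e-12, ptol = 1e-12))
    new_params <- stats::coef(fit)
    delta <- max(abs(new_params - unlist(params)) /
                   pmax(abs(unlist(params)), 1e-8))
    params <- as.list(new_params)
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(fit = fit, params = params, n_iter = iter, converged = converged)
}

#' Fit a cumulative-lognormal dose-response curve
#'
#' Fits response rate against mean dose with the mean function
#' `Lambda(x; mu, sigma) = pnorm((log x - mu)/sigma)` by iteratively
#' reweighted nonlinear least squares (binomial weights from the current
#' fitted rates). `sigma` is optimised on the log scale to enforce
#' positivity and reported on the natural scale (delta-method SE).
#' Standard errors come from the weighted least-squares curvature at the
#' optimum, scaled by `sqrt(deviance/df)`.
#'
#' @param points Data frame with columns `mean_dose`, `rate`, `trials`
#'   (e.g. a [run_sweep()] result); at least 3 points.
#' @param init Optional numeric `c(mu, sigma)` starting value. By default a
#'   probit-transform linear regression of `qnorm(rate)` on `log(mean_dose)`
#'   supplies the start, falling back to the sweep's threshold parameters.
#' @param max_iter,tol Outer-reweighting iteration cap and relative
#'   parameter-change tolerance.
#' @return A `dose_response_fit` with estimates `mu`, `sigma`.
#' @examples
#' sw <- run_sweep(sweep_config(n_trials = 1e5, seed = 3))
#' fit_cumulative_lognormal(sw)
#' @export
fit_cumulative_lognormal <- function(points, init = NULL, max_iter = 50,
                                     tol = 1e-8) {
  points <- as_sweep_points(points)
  if (nrow(points) < 3) stop("need at least 3 points")
  start <- lognormal_start(points, init)
  mean_fun <- function(p, x) stats::plnorm(x, p[["mu"]], exp(p[["lsig"]]))
  attr(mean_fun, "formula") <- y ~ stats::plnorm(x, mu, exp(lsig))
  res <- irls_loop(points, mean_fun,
                   start = list(mu = start[1], lsig = log(start[2])),
                   max_iter = max_iter, tol = tol)
  cf <- stats::coef(res$fit)
  se <- summary(res$fit)$coefficients[, "Std. Error"]
  sigma_hat <- exp(cf[["lsig"]])
  estimates <- c(mu = cf[["mu"]], sigma = sigma_hat)
  std_errors <- c(mu = se[["mu"]], sigma = sigma_hat * se[["lsig"]])
  fitted <- mean_fun(as.list(cf), points$mean_dose)
  dev <- weighted_deviance(points, fitted)
  if (!res$converged)
    stop(sprintf(paste("cumulative-lognormal fit did not converge in %d",
                       "reweighting iterations (last mu = %.4f, sigma = %.4f)"),
                 max_iter, estimates[["mu"]], estimates[["sigma"]]))
  new_fit_result("cumulative_lognormal", estimates, std_errors, dev,
                 nrow(points) - 2L, res$converged, res$n_iter, fitted, points)
}

lognormal_start <- function(points, init) {
  if (!is.null(init)) {
    stopifnot(is.numeric(init), length(init) == 2L, init[2] > 0)
    return(as.numeric(init))
  }
  ok <- points$rate > 0 & points$rate < 1
  if (sum(ok) >= 2) {
    z <- stats::qnorm(points$rate[ok])
    co <- stats::coef(stats::lm(z ~ log(points$mean_dose[ok])))
    slope <- co[[2L]]
    if (is.finite(slope) && slope > 0)
      return(c(-co[[1L]] / slope, 1 / slope))
  }
  cfg <- attr(points, "config")
  if (!is.null(cfg))
    return(c(cfg$threshold$mu, sqrt(cfg$sigma1^2 + cfg$threshold$sigma^2)))
  c(log(stats::median(points$mean_dose)), 0.5)
}

#' Fit a power-law dose-response curve
#'
#' Fits `rate = a * mean_dose^b` with the same iteratively reweighted
#' scheme as [fit_cumulative_lognormal()]. `a` is optimised as `log(a)` to
#' enforce positivity; the start comes from ordinary least squares on the
#' log-log points with positive rates.
#'
#' @inheritParams fit_cumulative_lognormal
#' @return A `dose_response_fit` with estimates `a`, `b`.
#' @export
fit_power_law <- function(points, max_iter = 50, tol = 1e-8) {
  points <- as_sweep_points(points)
  if (nrow(points) < 3) stop("need at least 3 points")
  pos <- points$rate > 0
  if (!any(pos)) stop("all rates are zero; power law cannot be initialised")
  co <- stats::coef(stats::lm(log(points$rate[pos]) ~
                                log(points$mean_dose[pos])))
  mean_fun <- function(p, x) exp(p[["la"]]) * x^p[["b"]]
  attr(mean_fun, "formula") <- y ~ exp(la) * x^b
  res <- irls_loop(points, mean_fun,
                   start = list(la = co[[1L]], b = co[[2L]]),
                   max_iter = max_iter, tol = tol)
  cf <- stats::coef(res$fit)
  se <- summary(res$fit)$coefficients[, "Std. Error"]
  a_hat <- exp(cf[["la"]])
  estimates <- c(a = a_hat, b = cf[["b"]])
  std_errors <- c(a = a_hat * se[["la"]], b = se[["b"]])
  fitted <- mean_fun(as.list(cf), points$mean_dose)
  dev <- weighted_deviance(points, clamp_rate(fitted))
  if (!res$converged)
    stop(sprintf("power-law fit did not converge in %d reweighting iterations",
                 max_iter))
  new_fit_result("power_law", estimates, std_errors, dev,
                 nrow(points) - 2L, res$converged, res$n_iter, fitted, points)
}

#' Weighted deviance of fitted response rates
#'
#' `sum(w_i (y_i - p_i)^2)` with binomial weights
#' `w_i = N_i/(p_i (1 - p_i))` taken from the fitted rates `p_i`. This is
#' the Pearson-type discrepancy the iteratively reweighted fits minimise;
#' at the true model it is distributed approximately chi-squared with one
#' degree of freedom per point.
#'
#' @param points Data frame with `rate` and `trials` (and `mean_dose`).
#' @param fitted_rates Fitted rates in (0, 1), aligned with `points`.
#' @return Non-negative scalar; 0 iff the fit is perfect.
#' @export
weighted_deviance <- function(points, fitted_rates) {
  points <- as_sweep_points(points)
  if (length(fitted_rates) != nrow(points))
    stop("fitted_rates length must match points")
  if (any(fitted_rates <= 0 | fitted_rates >= 1))
    stop("fitted rates must lie strictly in (0, 1)")
  w <- binomial_weights(fitted_rates, points$trials)
  sum(w * (points$rate - fitted_rates)^2)
}

#' Compare two fitted dose-response models
#'
#' Deterministic record of which model attains the smaller deviance at
#' equal degrees of freedom.
#'
#' @param a,b `dose_response_fit` objects on the same points.
#' @return List of class `model_comparison` with both deviances, the shared
#'   `df`, and `preferred` (one of the model names, or `"none"` on a tie).
#' @export
compare_models <- function(a, b) {
  stopifnot(inherits(a, "dose_response_fit"), inherits(b, "dose_response_fit"))
  if (a$df != b$df) stop("models have different degrees of freedom")
  preferred <- if (a$deviance < b$deviance) a$model
               else if (b$deviance < a$deviance) b$model
               else "none"
  structure(list(deviance_a = a$deviance, model_a = a$model,
                 deviance_b = b$deviance, model_b = b$model,
                 df = a$df, preferred = preferred),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("%s: deviance = %.3g; %s: deviance = %.3g (df = %d)\n",
              x$model_a, x$deviance_a, x$model_b, x$deviance_b, x$df))
  cat("Preferred:", x$preferred, "\n")
  invisible(x)
}

#' F-test between nested weighted fits
#'
#' `F = ((dev_reduced - dev_full)/delta_df) / (dev_full/df_full)` with the
#' p-value from the F distribution on `(delta_df, df_full)` degrees of
#' freedom. Used both for the power-law vs lognormal shape question and
#' for the cesium-term test of the epidemiological stage.
#'
#' @param full,reduced Fit objects (anything with `deviance` and `df`
#'   fields); the reduced model must be nested in the full one.
#' @return List with `statistic`, `df1`, `df2`, `p_value`.
#' @export
f_test <- function(full, reduced) {
  stopifnot(is.numeric(full$deviance), is.numeric(reduced$deviance))
  if (full$deviance <= 0) stop("full-model deviance must be positive")
  df1 <- reduced$df - full$df
  if (df1 < 1) stop("reduced model must have fewer parameters than the full")
  f <- ((reduced$deviance - full$deviance) / df1) / (full$deviance / full$df)
  p <- stats::pf(max(f, 0), df1, full$df, lower.tail = FALSE)
  list(statistic = f, df1 = df1, df2 = full$df, p_value = p)
}

#' Dispersion-ratio table
#'
#' For each sweep point, the fitted response rate at its mean dose
#' (`predicted_with`, the curve estimated *with* dose dispersion) is
#' compared with the no-dispersion prediction, the threshold cdf
#' `(mu2, sigma2)` evaluated at the same mean dose (`predicted_without`).
#' Their ratio quantifies how strongly dose dispersion amplifies low-dose
#' response rates; it decreases towards 1 as dose grows.
#'
#' @param sweep A [run_sweep()] result (or compatible data frame with
#'   `mu1`, `mean_dose`).
#' @param fit A converged cumulative-lognormal `dose_response_fit` of the
#'   sweep.
#' @param threshold [lognormal_params()] of the threshold distribution
#'   (the `sigma1 = 0` reference curve); defaults to the sweep's config.
#' @return Data frame with columns `mu1`, `mean_dose`, `predicted_with`,
#'   `predicted_without`, `ratio`.
#' @export
dispersion_ratio_table <- function(sweep, fit, threshold = NULL) {
  stopifnot(inherits(fit, "dose_response_fit"))
  if (fit$model != "cumulative_lognormal")
    stop("dispersion ratios are defined for the cumulative-lognormal fit")
  if (!isTRUE(fit$converged)) stop("fit has not converged")
  if (is.null(threshold)) {
    cfg <- attr(sweep, "config")
    if (is.null(cfg)) stop("no threshold given and sweep carries no config")
    threshold <- cfg$threshold
  }
  threshold <- as_lognormal_params(threshold)
  sweep <- as.data.frame(sweep)
  curve <- lognormal_params(fit$estimates[["mu"]], fit$estimates[["sigma"]])
  p_with <- lognormal_cdf(sweep$mean_dose, curve)
  p_without <- lognormal_cdf(sweep$mean_dose, threshold)
  data.frame(mu1 = sweep$mu1, mean_dose = sweep$mean_dose,
             predicted_with = p_with, predicted_without = p_without,
             ratio = p_with / p_without)
}
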