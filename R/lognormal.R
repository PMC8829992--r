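#' Lognormal distribution parameters
#'
#' Constructs a validated parameter pair for a lognormal distribution on the
#' dose (or body-burden) axis. `mu` is the natural logarithm of the median
#' and `sigma` the log-scale standard deviation. `sigma = 0` is permitted
#' and denotes the degenerate "discrete dose" case, a point mass at
#' `exp(mu)`; every consumer in the package handles it.
#'
#' Two such pairs drive the threshold-exceedance model: one for the
#' population dose distribution (`mu1`, `sigma1`) and one for the
#' distribution of individual threshold doses, i.e. radiosensitivities
#' (`mu2`, `sigma2`).
#'
#' @param mu Real; natural log of the median (log-mSv for doses, log-Bq/kg
#'   for burdens — units are carried as labels only, never converted).
#' @param sigma Non-negative real; log-scale standard deviation.
#' @return An object of class `lognormal_params`.
#' @examples
#' thr <- lognormal_params(log(10), 0.4)   # median threshold 10 mSv
#' exp(thr$mu)
#' @export
lognormal_params <- function(mu, sigma) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(sigma), length(sigma) == 1L, is.finite(sigma))
  if (sigma < 0) stop("sigma must be non-negative")
  structure(list(mu = mu, sigma = sigma), class = "lognormal_params")
}

#' @export
print.lognormal_params <- function(x, ...) {
  cat(sprintf("Lognormal(mu = %.4g, sigma = %.4g); median = %.4g\n",
              x$mu, x$sigma, exp(x$mu)))
  invisible(x)
}

as_lognormal_params <- function(x) {
  if (inherits(x, "lognormal_params")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(lognormal_params(x[[1L]], x[[2L]]))
  stop("expected a lognormal_params object or a numeric (mu, sigma) pair")
}

#' Lognormal probability density
#'
#' Density of the dose distribution,
#' \deqn{f(x;\mu,\sigma) = \frac{1}{x\sigma\sqrt{2\pi}}
#'   \exp\!\left(-\frac{(\log x-\mu)^2}{2\sigma^2}\right),}
#' with the natural logarithm throughout. Undefined for the degenerate
#' point-mass case `sigma = 0` (an error): the discrete-dose limit is only
#' needed through the cdf.
#'
#' @param x Positive dose(s).
#' @param params A [lognormal_params()] object with `sigma > 0`.
#' @return Density per dose unit, same length as `x`.
#' @export
lognormal_pdf <- function(x, params) {
  params <- as_lognormal_params(params)
  if (params$sigma <= 0) stop("lognormal_pdf requires sigma > 0")
  if (any(!is.finite(x)) || any(x <= 0)) stop("x must be positive")
  stats::dlnorm(x, meanlog = params$mu, sdlog = params$sigma)
}

#' Lognormal cumulative distribution
#'
#' `P(X <= x)`, equal to `pnorm((log(x) - mu)/sigma)` for `sigma > 0` and a
#' unit step at the median `exp(mu)` for the degenerate `sigma = 0` case.
#'
#' @inheritParams lognormal_pdf
#' @param params A [lognormal_params()] object; `sigma = 0` allowed.
#' @return Probabilities in \[0, 1\].
#' @export
lognormal_cdf <- function(x, params) {
  params <- as_lognormal_params(params)
  if (any(!is.finite(x)) || any(x <= 0)) stop("x must be positive")
  if (params$sigma == 0) return(as.numeric(x >= exp(params$mu)))
  stats::plnorm(x, meanlog = params$mu, sdlog = params$sigma)
}

#' Probability that a random dose exceeds a random threshold
#'
#' For independent lognormal dose `X1 ~ (mu1, sigma1)` and threshold
#' `X2 ~ (mu2, sigma2)`, `log X1 - log X2` is normal, so
#' \deqn{P(X_1 > X_2) = \Phi\!\left(\frac{\mu_1-\mu_2}
#'   {\sqrt{\sigma_1^2+\sigma_2^2}}\right).}
#' This closed form is the analytic oracle the Monte Carlo simulator is
#' checked against. With both sigmas zero the comparison is deterministic
#' (0, 1, or 1/2 on the tie `mu1 == mu2`).
#'
#' @param dose,threshold [lognormal_params()] objects.
#' @return Probability in \[0, 1\]; exactly 0.5 when the medians agree and
#'   at least one sigma is positive.
#' @export
exceedance_probability <- function(dose, threshold) {
  dose <- as_lognormal_params(dose)
  threshold <- as_lognormal_params(threshold)
  s <- sqrt(dose$sigma^2 + threshold$sigma^2)
  d <- dose$mu - threshold$mu
  if (s == 0) return(if (d > 0) 1 else if (d < 0) 0 else 0.5)
  stats::pnorm(d / s)
}

#' Derived cumulative-lognormal dose-response curve
#'
#' The threshold-exceedance model implies that the response rate, plotted
#' against the *mean* dose of each dose distribution, follows a cumulative
#' lognormal with location `mu = mu2 + sigma1^2/2` and spread
#' `sigma = sqrt(sigma1^2 + sigma2^2)`. The `sigma1^2/2` shift is the gap
#' between the log-median and the log of the mean of the dose distribution;
#' with `sigma1 = 0` the curve reduces to the no-dispersion threshold cdf
#' `(mu2, sigma2)`.
#'
#' @param sigma1 Non-negative spread of the dose distribution.
#' @param threshold [lognormal_params()] for the threshold (radiosensitivity)
#'   distribution; `sigma > 0` required.
#' @return An object of class `response_curve` with fields `mu`, `sigma`.
#' @examples
#' derived_response_curve(0.3, lognormal_params(log(10), 0.4))
#' @export
derived_response_curve <- function(sigma1, threshold) {
  threshold <- as_lognormal_params(threshold)
  stopifnot(is.numeric(sigma1), length(sigma1) == 1L, sigma1 >= 0)
  if (threshold$sigma <= 0) stop("threshold sigma must be positive")
  structure(list(mu = threshold$mu + sigma1^2 / 2,
                 sigma = sqrt(sigma1^2 + threshold$sigma^2)),
            class = "response_curve")
}

#' @export
print.response_curve <- function(x, ...) {
  cat(sprintf("Cumulative-lognormal response curve: mu = %.4f, sigma = %.4f\n",
              x$mu, x$sigma))
  invisible(x)
}

#' Evaluate a response curve at given doses
#'
#' @param curve A `response_curve` (or anything coercible to
#'   [lognormal_params()]).
#' @param x Positive dose(s), on the mean-dose axis.
#' @return Response rates in (0, 1).
#' @export
response_rate <- function(curve, x) {
  lognormal_cdf(x, lognormal_params(curve$mu, curve$sigma))
}

#' Mean of a lognormal dose distribution
#'
#' First moment `exp(mu + sigma^2/2)`; the analytic counterpart of the
#' simulated sample mean dose. Equals the point mass `exp(mu)` when
#' `sigma = 0`.
#'
#' @param dose A [lognormal_params()] object.
#' @return Mean dose (same units as `exp(mu)`).
#' @export
expected_mean_dose <- function(dose) {
  dose <- as_lognormal_params(dose)
  exp(dose$mu + dose$sigma^2 / 2)
}
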