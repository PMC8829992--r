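#' Configuration for a dose-median sweep
#'
#' Bundles the grid of dose-distribution log-medians `mu1`, the dose spread
#' `sigma1`, the threshold (radiosensitivity) distribution, the number of
#' Monte Carlo trials per grid point, and the seed. The defaults are the
#' reference study conditions: `mu1 = 0, 0.1, ..., 1.0` (11 points),
#' `sigma1 = 0.3`, threshold median 10 mSv (`mu2 = log 10`) with
#' `sigma2 = 0.4`, and one million trials per point.
#'
#' @param mu1_grid Strictly increasing numeric grid of log-median doses.
#' @param sigma1 Non-negative dose-distribution spread.
#' @param threshold [lognormal_params()] of the threshold distribution.
#' @param n_trials Trials per grid point (N), a positive integer.
#' @param seed Integer seed; all randomness of the sweep flows from it.
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(mu1_grid = seq(0, 1, by = 0.1),
                         sigma1 = 0.3,
                         threshold = lognormal_params(log(10), 0.4),
                         n_trials = 1e6,
                         seed = 1L) {
  stopifnot(is.numeric(mu1_grid), length(mu1_grid) >= 1L,
            all(is.finite(mu1_grid)))
  if (is.unsorted(mu1_grid, strictly = TRUE))
    stop("mu1_grid must be strictly increasing")
  stopifnot(is.numeric(sigma1), length(sigma1) == 1L, sigma1 >= 0)
  n_trials <- as_count(n_trials, "n_trials")
  seed <- as_seed(seed)
  structure(list(mu1_grid = as.numeric(mu1_grid), sigma1 = sigma1,
                 threshold = as_lognormal_params(threshold),
                 n_trials = n_trials, seed = seed),
            class = "sweep_config")
}

as_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1 ||
      x != floor(x))
    stop(sprintf("%s must be a positive integer", name))
  x
}

as_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed) ||
      seed != floor(seed))
    stop("seed must be an integer")
  as.integer(seed %% .Machine$integer.max)
}

#' Monte Carlo threshold-exceedance count for one dose distribution
#'
#' Draws `n_trials` independent pairs (dose, threshold), one pair per
#' trial, and counts the trials in which the dose exceeds the individual
#' threshold — the adverse outcomes of the All-or-None repair model. Also
#' returns the sample mean dose, the abscissa of the dose-response plots.
#'
#' @param dose,threshold [lognormal_params()] objects (`sigma = 0` gives
#'   degenerate point-mass draws).
#' @param n_trials Number of paired draws N.
#' @param seed Optional integer seed; when supplied the result is
#'   reproducible, otherwise the current RNG stream is used.
#' @return List with `events` (integer count), `mean_dose`, `trials`, and
#'   `rate = events/trials`.
#' @examples
#' simulate_exceedance(lognormal_params(1, 0.3),
#'                     lognormal_params(log(10), 0.4),
#'                     n_trials = 1e5, seed = 1)
#' @export
simulate_exceedance <- function(dose, threshold, n_trials, seed = NULL) {
  dose <- as_lognormal_params(dose)
  threshold <- as_lognormal_params(threshold)
  n_trials <- as_count(n_trials, "n_trials")
  if (!is.null(seed)) set.seed(as_seed(seed))
  x1 <- stats::rlnorm(n_trials, meanlog = dose$mu, sdlog = dose$sigma)
  x2 <- stats::rlnorm(n_trials, meanlog = threshold$mu, sdlog = threshold$sigma)
  events <- sum(x1 > x2)
  list(events = as.integer(events), mean_dose = mean(x1),
       trials = n_trials, rate = events / n_trials)
}

#' Run a dose-median sweep
#'
#' For each grid value `mu1` the simulator draws a fresh set of `n_trials`
#' (dose, threshold) pairs — no dose sample is reused across grid points —
#' and records the event count, mean dose, and response rate. The result is
#' the raw material for the cumulative-lognormal and power-law fits.
#'
#' @param config A [sweep_config()].
#' @return A `data.frame` of class `dose_sweep` with columns `mu1`,
#'   `mean_dose`, `events`, `trials`, `rate` (one row per grid value),
#'   carrying the config as attribute `config`.
#' @examples
#' sw <- run_sweep(sweep_config(n_trials = 1e4, seed = 7))
#' sw$rate
#' @export
run_sweep <- function(config) {
  if (!inherits(config, "sweep_config")) stop("config must be a sweep_config")
  set.seed(config$seed)
  rows <- lapply(config$mu1_grid, function(m1) {
    sim <- simulate_exceedance(lognormal_params(m1, config$sigma1),
                               config$threshold, config$n_trials)
    data.frame(mu1 = m1, mean_dose = sim$mean_dose, events = sim$events,
               trials = sim$trials, rate = sim$rate)
  })
  out <- do.call(rbind, rows)
  attr(out, "config") <- config
  class(out) <- c("dose_sweep", "data.frame")
  out
}

#' Replicate study of the fitted spread parameter
#'
#' Repeats the full sweep-plus-fit pipeline `n_reps` times with independent
#' seed streams, collecting the fitted spread `sigma_hat` of the cumulative
#' lognormal from each replicate. Per replicate it computes
#' `z = (sigma_hat - sigma_expected)/SE` with
#' `sigma_expected = sqrt(sigma1^2 + sigma2^2)`; the mean deviation of the
#' estimates and its standard error summarise whether the spread relation
#' holds.
#'
#' @param config A [sweep_config()]; replicate r uses seed
#'   `config$seed + r`.
#' @param n_reps Number of replicates (>= 2).
#' @param fit Fitting function applied to each replicate sweep; defaults to
#'   [fit_cumulative_lognormal()].
#' @return Object of class `replicate_sigma_study`: `sigma_hats`, `ses`,
#'   `z_scores`, `sigma_expected`, `mean_deviation`, `se_mean_deviation`,
#'   and `failed` (indices of non-converged replicates, excluded from the
#'   summaries).
#' @export
replicate_sigma_study <- function(config, n_reps = 10,
                                  fit = fit_cumulative_lognormal) {
  if (!inherits(config, "sweep_config")) stop("config must be a sweep_config")
  n_reps <- as_count(n_reps, "n_reps")
  if (n_reps < 2) stop("n_reps must be at least 2")
  sigma_expected <- sqrt(config$sigma1^2 + config$threshold$sigma^2)
  sigma_hats <- ses <- rep(NA_real_, n_reps)
  failed <- integer(0)
  for (r in seq_len(n_reps)) {
    cfg_r <- config
    cfg_r$seed <- as_seed(config$seed + r)
    fr <- tryCatch(fit(run_sweep(cfg_r)), error = function(e) NULL)
    if (is.null(fr) || !isTRUE(fr$converged)) {
      failed <- c(failed, r)
      next
    }
    sigma_hats[r] <- fr$estimates[["sigma"]]
    ses[r] <- fr$std_errors[["sigma"]]
  }
  ok <- !is.na(sigma_hats)
  if (sum(ok) < 2) stop("fewer than two replicates converged")
  z <- (sigma_hats - sigma_expected) / ses
  structure(list(sigma_hats = sigma_hats[ok], ses = ses[ok],
                 z_scores = z[ok], sigma_expected = sigma_expected,
                 mean_deviation = mean(sigma_hats[ok]) - sigma_expected,
                 se_mean_deviation = stats::sd(sigma_hats[ok]) / sqrt(sum(ok)),
                 failed = failed),
            class = "replicate_sigma_study")
}

#' @export
print.replicate_sigma_study <- function(x, ...) {
  cat(sprintf("Replicate sigma study (%d replicates, expected sigma = %.4f)\n",
              length(x$sigma_hats), x$sigma_expected))
  print(round(rbind(estimate = x$sigma_hats, SE = x$ses,
                    z = x$z_scores), 4))
  cat(sprintf("Mean deviation: %.4f +/- %.4f\n",
              x$mean_deviation, x$se_mean_deviation))
  if (length(x$failed))
    cat("Non-converged replicates excluded:", x$failed, "\n")
  invisible(x)
}
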