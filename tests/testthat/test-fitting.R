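test_that("noise-free cumulative-lognormal points are recovered exactly", {
  x <- exp(seq(0, 1.1, by = 0.1))
  pts <- noise_free_points(x, function(x) plnorm(x, 2.348, 0.5))
  fit <- fit_cumulative_lognormal(pts)
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates[["mu"]]), 2.348, tolerance = 1e-6)
  expect_equal(unname(fit$estimates[["sigma"]]), 0.5, tolerance = 1e-6)
  expect_lt(fit$deviance, 1e-10)
  expect_equal(fit$df, length(x) - 2L)
})

test_that("noise-free power-law points are recovered exactly", {
  x <- seq(0.2, 0.7, by = 0.05)
  pts <- noise_free_points(x, function(x) 2 * x^3)
  fit <- fit_power_law(pts)
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates[["a"]]), 2, tolerance = 1e-8)
  expect_equal(unname(fit$estimates[["b"]]), 3, tolerance = 1e-8)
})

test_that("simulated sweeps recover the derived parameter relations", {
  # averaged over replicates, mu_hat -> mu2 + sigma1^2/2 and
  # sigma_hat -> sqrt(sigma1^2 + sigma2^2)
  mus <- sigmas <- numeric(10)
  for (r in 1:10) {
    sw <- run_sweep(sweep_config(n_trials = 2e5, seed = 600 + r))
    fit <- fit_cumulative_lognormal(sw)
    mus[r] <- fit$estimates[["mu"]]
    sigmas[r] <- fit$estimates[["sigma"]]
  }
  expect_lt(abs(mean(mus) - 2.348), 4 * sd(mus) / sqrt(10))
  expect_lt(abs(mean(sigmas) - 0.5), 4 * sd(sigmas) / sqrt(10))
  expect_lt(sd(mus), 0.1)
})

test_that("weighted deviance behaves like a Pearson discrepancy", {
  x <- exp(seq(0.2, 1, by = 0.2))
  pts <- noise_free_points(x, function(x) plnorm(x, 2.348, 0.5))
  expect_equal(weighted_deviance(pts, pts$rate), 0)
  expect_error(weighted_deviance(pts, rep(0, nrow(pts))), "strictly")
  expect_error(weighted_deviance(pts, pts$rate[-1]), "length")
  # order invariance
  sw <- run_sweep(sweep_config(n_trials = 5e4, seed = 71))
  fit <- fit_cumulative_lognormal(sw)
  idx <- sample(nrow(sw))
  expect_equal(weighted_deviance(sw[idx, ], fit$fitted_rates[idx]),
               weighted_deviance(sw, fit$fitted_rates))
})

test_that("true-rate deviance of simulated points is chi-squared-like", {
  # five moderate-rate points, 200 replicates: mean ~ k, variance ~ 2k
  thr <- lognormal_params(log(10), 0.4)
  mu1 <- seq(1.8, 2.6, by = 0.2)
  p_true <- vapply(mu1, function(m)
    exceedance_probability(lognormal_params(m, 0.3), thr), numeric(1))
  n <- 1000
  set.seed(808)
  devs <- replicate(200, {
    events <- rbinom(length(p_true), n, p_true)
    pts <- data.frame(mean_dose = exp(mu1), rate = events / n, trials = n)
    weighted_deviance(pts, p_true)
  })
  expect_lt(abs(mean(devs) - length(p_true)), 1)
  expect_gt(sd(devs), 1)
})

test_that("model comparison prefers the smaller deviance at equal df", {
  sw <- run_sweep(sweep_config(n_trials = 2e5, seed = 81))
  fl <- fit_cumulative_lognormal(sw)
  fp <- fit_power_law(sw)
  cmp <- compare_models(fl, fp)
  expect_equal(cmp$df, 9L)
  expect_equal(cmp$preferred, "cumulative_lognormal")
  tie <- compare_models(fl, fl)
  expect_equal(tie$preferred, "none")
  fp_bad <- fp
  fp_bad$df <- 5L
  expect_error(compare_models(fl, fp_bad), "degrees of freedom")
})

test_that("F-test is one at equal deviance and errors sensibly", {
  full <- list(deviance = 10, df = 9)
  expect_equal(f_test(full, list(deviance = 10, df = 12))$p_value, 1)
  expect_error(f_test(list(deviance = 0, df = 9), full), "positive")
  expect_error(f_test(full, list(deviance = 12, df = 9)), "fewer")
  out <- f_test(full, list(deviance = 40, df = 12))
  expect_true(out$p_value > 0 && out$p_value < 0.05)
})

test_that("dispersion ratios decrease with dose and collapse at sigma1=0", {
  sw <- run_sweep(sweep_config(n_trials = 2e5, seed = 91))
  fit <- fit_cumulative_lognormal(sw)
  tab <- dispersion_ratio_table(sw, fit)
  expect_equal(nrow(tab), nrow(sw))
  expect_true(all(diff(tab$ratio) < 0))
  expect_equal(tab$ratio, tab$predicted_with / tab$predicted_without)
  # when the fitted curve IS the no-dispersion curve, all ratios are 1
  x <- exp(seq(0, 1, by = 0.1))
  pts <- noise_free_points(x, function(x) plnorm(x, log(10), 0.4))
  fit0 <- fit_cumulative_lognormal(pts)
  tab0 <- dispersion_ratio_table(cbind(pts, mu1 = log(x)), fit0,
                                 lognormal_params(log(10), 0.4))
  expect_equal(tab0$ratio, rep(1, length(x)), tolerance = 1e-6)
  expect_error(dispersion_ratio_table(sw, fit_power_law(sw)), "lognormal")
})
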