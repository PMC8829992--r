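test_that("burden curve rises from zero to a sub-40 peak then decays", {
  b <- default_burden_curve(60)
  expect_equal(b[1:6], rep(0, 6))
  expect_lt(max(b), 40)
  expect_equal(which.max(b), 18L)
  expect_true(all(diff(b[18:60]) < 0))
  expect_true(all(b >= 0))
})

test_that("null series matches its baseline within Poisson noise", {
  es <- generate_epi_series(truth = list(amplitude = 0), seed = 42)
  t <- es$period
  expected <- es$births * (6 / 1000) * exp(log(0.98) / 12 * (t - 1))
  expect_lt(abs(sum(es$deaths) - sum(expected)), 4 * sqrt(sum(expected)))
  expect_true(all(es$deaths <= es$births))
  # reproducibility
  expect_identical(es, generate_epi_series(truth = list(amplitude = 0),
                                           seed = 42))
})

test_that("an excess median far above the burden range is a null in disguise", {
  # with exp(mu) >> max burden the excess term is < 1 % of baseline
  es <- generate_epi_series(truth = list(mu = 8), seed = 43)
  null_expected <- sum(es$births * (6 / 1000) *
                         exp(log(0.98) / 12 * (es$period - 1)))
  expect_lt(abs(sum(es$deaths) - null_expected),
            0.01 * null_expected + 4 * sqrt(null_expected))
})

test_that("total deaths under the effect model satisfy Poisson conservation", {
  es <- generate_epi_series(seed = 44)
  truth <- attr(es, "truth")
  spec <- attr(es, "spec")
  lagged <- teratodose:::lag_burden(es$burden, spec$lag)
  rate <- teratodose:::epi_true_rate(truth, spec, es$period, lagged)
  total <- sum(es$births * rate)
  expect_gt(total, sum(es$births * 6 / 1000 *
                         exp(log(0.98) / 12 * (es$period - 1))))
  expect_lt(abs(sum(es$deaths) - total), 3 * sqrt(total))
  expect_error(generate_epi_series(truth = list(baseline_rate = 1500)),
               "rates outside")
})

test_that("epi fit detects the exposure term and nests the reduced model", {
  es <- generate_epi_series(seed = 11)
  fit <- fit_epi_model(es)
  expect_true(fit$converged)
  expect_lt(fit$p_cesium, 0.05)
  expect_equal(fit$df, 60L - 5L)
  expect_equal(fit$reduced$df, 60L - 2L)
  expect_gte(fit$reduced$deviance, fit$deviance)
  expect_true(all(fit$fitted_rates > 0))
  expect_true(all(is.finite(fit$std_errors)))
  # all-zero burden: amplitude unidentifiable
  flat <- generate_epi_series(truth = list(amplitude = 0), seed = 2,
                              burden_curve = rep(0, 60))
  expect_error(fit_epi_model(flat), "unidentifiable")
})

test_that("null fit finds no significant exposure term", {
  es <- generate_epi_series(truth = list(amplitude = 0), seed = 5003)
  fit <- fit_epi_model(es)
  expect_gt(fit$p_cesium, 0.05)
  # amplitude consistent with zero at 3 SE
  expect_lt(abs(fit$amplitude), 3 * fit$std_errors[["A"]] + 1e-6)
})

test_that("rate ratios are calibrated under the null and ordered under effect", {
  es0 <- generate_epi_series(truth = list(amplitude = 0), seed = 52)
  fit0 <- fit_epi_model(es0)
  rr0 <- rate_ratio_curve(es0, fit0)
  cover <- mean(abs(rr0$ratio - 1) <= 2 * rr0$sd, na.rm = TRUE)
  expect_gte(cover, 0.85)
  expect_equal(rr0$sd, rr0$ratio / sqrt(es0$deaths))
  # effect: high lagged burdens sit above low lagged burdens
  es1 <- generate_epi_series(seed = 53)
  fit1 <- fit_epi_model(es1)
  rr1 <- rate_ratio_curve(es1, fit1)
  expect_gt(mean(rr1$ratio[rr1$burden > 25]),
            mean(rr1$ratio[rr1$burden < 12.5]))
})

test_that("rate ratios of the model's own rates reproduce 1 + A*Lambda", {
  spec <- epi_model_spec()
  n <- 48L
  burden <- default_burden_curve(n)
  lagged <- teratodose:::lag_burden(burden, spec$lag)
  b0 <- log(0.006); b1 <- -0.0017; A <- 1.2; mu <- 3.9; sigma <- 0.35
  t <- seq_len(n)
  full_rate <- exp(b0 + b1 * (t - 1)) *
    (1 + A * teratodose:::lognormal_cdf_safe(lagged, mu, sigma))
  records <- data.frame(period = t, births = 50000,
                        deaths = 50000 * full_rate, burden = burden)
  fit <- structure(list(spec = spec, amplitude = A, mu = mu, sigma = sigma,
                        reduced = list(coefficients = c(b0 = b0, b1 = b1))),
                   class = "epi_fit")
  rr <- rate_ratio_curve(records, fit)
  expect_equal(rr$ratio,
               1 + A * teratodose:::lognormal_cdf_safe(lagged, mu, sigma),
               tolerance = 1e-10)
})

test_that("practical threshold follows the closed-form inverse cdf", {
  fit <- structure(list(amplitude = 1, mu = 3.97, sigma = 0.30),
                   class = "epi_fit")
  expect_equal(as.numeric(practical_threshold(fit, 0.05)),
               32.34773, tolerance = 1e-5)
  expect_equal(as.numeric(practical_threshold(fit, 0.05)),
               exp(3.97 + 0.30 * qnorm(0.05)))
  # no true threshold: epsilon -> 0 sends the practical threshold to 0
  expect_lt(as.numeric(practical_threshold(fit, 1e-200)), 0.01)
  # monotone in epsilon
  eps <- c(0.01, 0.05, 0.2, 0.5)
  thr <- vapply(eps, function(e) as.numeric(practical_threshold(fit, e)),
                numeric(1))
  expect_true(all(diff(thr) > 0))
  # larger sigma lowers the epsilon = 0.05 threshold at fixed mu
  wide <- structure(list(amplitude = 1, mu = 3.97, sigma = 0.6),
                    class = "epi_fit")
  expect_lt(as.numeric(practical_threshold(wide, 0.05)),
            as.numeric(practical_threshold(fit, 0.05)))
  # never reached, and no-excess signalling
  expect_equal(as.numeric(practical_threshold(fit, 2)), Inf)
  none <- structure(list(amplitude = 0, mu = 3.97, sigma = 0.3),
                    class = "epi_fit")
  expect_error(practical_threshold(none), class = "no_threshold_error")
})

test_that("misspecifying the lag does not improve the fit on average", {
  devs <- sapply(1:6, function(r) {
    es <- generate_epi_series(seed = 700 + r)
    c(true = fit_epi_model(es, epi_model_spec(lag = 7))$deviance,
      wrong = fit_epi_model(es, epi_model_spec(lag = 10))$deviance)
  })
  expect_lt(mean(devs["true", ]), mean(devs["wrong", ]))
})
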