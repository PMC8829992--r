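# Independent oracles used across the suite. These deliberately avoid the
# package's closed forms: exceedance probabilities come from 1-D quadrature
# of the threshold density against the dose survival function, and pdf
# normalisation from adaptive quadrature.

oracle_exceedance <- function(dose, threshold) {
  stats::integrate(function(x2)
    stats::dlnorm(x2, threshold$mu, threshold$sigma) *
      (1 - stats::plnorm(x2, dose$mu, dose$sigma)),
    lower = 0, upper = Inf, rel.tol = 1e-12)$value
}

# noise-free pseudo-sweep whose rates lie exactly on a given mean function
noise_free_points <- function(x, rate_fun, trials = 1e6) {
  data.frame(mean_dose = x, rate = rate_fun(x), trials = trials)
}

# random lognormal parameter pairs for property-style loops
random_params <- function(n, mu_range = c(-1, 3), sigma_range = c(0.05, 2)) {
  lapply(seq_len(n), function(i)
    lognormal_params(stats::runif(1, mu_range[1], mu_range[2]),
                     stats::runif(1, sigma_range[1], sigma_range[2])))
}
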