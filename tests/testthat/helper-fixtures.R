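# Shared helpers: tiny datasets built in code, and brute-force oracles
# kept deliberately independent of the package's fast implementations.

# random small survival dataset
rand_dataset <- function(N, n_groups = max(2L, N %/% 5L), seed = 1,
                         censor_prob = 0.2, with_x = TRUE) {
  set.seed(seed)
  survival_dataset(
    time = stats::rexp(N, 0.2),
    event = stats::rbinom(N, 1, 1 - censor_prob),
    group = sample.int(n_groups, N, replace = TRUE),
    covariates = if (with_x) data.frame(x = stats::rnorm(N)) else NULL)
}

# brute-force log partial likelihood: double loop over Eq-style risk sets
brute_force_pl <- function(time, event, eta) {
  out <- 0
  for (j in seq_along(time)) {
    if (event[j] == 1) {
      R <- which(time >= time[j])
      out <- out + eta[j] - log(sum(exp(eta[R])))
    }
  }
  out
}

# central finite-difference gradient of a scalar function
fd_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# likelihood closure that is identically zero (event-free limit)
null_loglik <- function(d) {
  function(W, hessian = TRUE) {
    list(value = 0, gradient = numeric(d),
         neg_hessian = if (hessian) matrix(0, d, d) else NULL)
  }
}

kidney_path <- function() {
  system.file("extdata", "kidney.csv", package = "coxaghq")
}

kidney_spec <- function() {
  kd <- read_survival_data(kidney_path())
  cox_model_spec(kd, linear = c("age", "sex", "GN", "AN", "PKD"),
                 frailty_prior = prior_exponential(median = 2),
                 beta_prior_variance = 1000)
}
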