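make_frailty_fit <- local({
  cache <- NULL
  function(B = 4000, seed = 2) {
    if (is.null(cache)) {
      d <- rand_dataset(40, n_groups = 8, seed = 61)
      spec <- cox_model_spec(d, linear = "x",
                             frailty_prior = prior_exponential(median = 1))
      cache <<- spec
    }
    fit_cox(cache, k = 7, B = B, seed = seed, theta_grid_points = 61)
  }
})

test_that("sampling is deterministic in the seed and differs across seeds", {
  f1 <- make_frailty_fit(B = 1000, seed = 5)
  f2 <- make_frailty_fit(B = 1000, seed = 5)
  expect_identical(f1$samples$draws, f2$samples$draws)
  f3 <- make_frailty_fit(B = 1000, seed = 6)
  expect_false(identical(f1$samples$draws, f3$samples$draws))
  # sigma marginals from different sampling seeds are close
  a <- sample_hyper_sd(f1, 1, B = 10000, seed = 1)
  b <- sample_hyper_sd(f1, 1, B = 10000, seed = 2)
  expect_lt(ks_statistic(a, b), 0.05)
})

test_that("single-component sampling reproduces its Gaussian", {
  set.seed(62)
  p <- 4
  mu <- rnorm(p)
  H <- crossprod(matrix(rnorm(p * p), p)) + diag(p)
  mix <- structure(
    list(components = list(list(theta = numeric(0), mean = mu,
                                chol_precision = chol(H))),
         phi = 1,
         spec = list(coef_names = paste0("w", 1:p), dim_W = p)),
    class = "cox_mixture_posterior")
  s <- sample_posterior(mix, B = 10000, seed = 3)
  Sg <- solve(H)
  se <- sqrt(diag(Sg) / 10000)
  expect_true(all(abs(colMeans(s$draws) - mu) < 4 * se))
  expect_equal(unname(stats::cov(s$draws)), Sg, tolerance = 0.15)
})

test_that("component frequencies follow the multinomial weights", {
  set.seed(63)
  p <- 2
  comps <- lapply(1:3, function(k) {
    list(theta = numeric(0), mean = rnorm(p), chol_precision = diag(p))
  })
  phi <- c(0.5, 0.3, 0.2)
  mix <- structure(
    list(components = comps, phi = phi,
         spec = list(coef_names = paste0("w", 1:p), dim_W = p)),
    class = "cox_mixture_posterior")
  s <- sample_posterior(mix, B = 10000, seed = 4)
  freq <- tabulate(s$component, 3) / 10000
  band <- 2.58 * sqrt(phi * (1 - phi) / 10000)   # 99% binomial bands
  expect_true(all(abs(freq - phi) < band))
})

test_that("constraint correction is exact, idempotent and matches theory", {
  set.seed(64)
  p <- 5
  mu <- rnorm(p)
  H <- crossprod(matrix(rnorm(p * p), p)) + diag(p)
  A <- c(1, 2, 0, -1, 3)
  mix <- structure(
    list(components = list(list(theta = numeric(0), mean = mu,
                                chol_precision = chol(H))),
         phi = 1,
         spec = list(coef_names = paste0("w", 1:p), dim_W = p,
                     blocks = list())),
    class = "cox_mixture_posterior")
  s <- sample_posterior(mix, B = 20000, seed = 5)
  sc <- apply_constraint(s, mix, A)
  expect_lt(max(abs(sc$draws %*% A)), 1e-8)
  # idempotence
  sc2 <- apply_constraint(sc, mix, A)
  expect_equal(sc$draws, sc2$draws, tolerance = 1e-10)
  # conditional-Gaussian oracle: condition the joint (x, Ax) analytically
  Sg <- solve(H)
  v <- drop(Sg %*% A)
  s2 <- drop(crossprod(A, v))
  mu_c <- mu - v * sum(A * mu) / s2
  Sg_c <- Sg - outer(v, v) / s2
  expect_true(all(abs(colMeans(sc$draws) - mu_c) <
                  4 * sqrt(pmax(diag(Sg_c), 1e-12) / 20000) + 1e-8))
  expect_equal(unname(stats::cov(sc$draws)), Sg_c, tolerance = 0.06)
  expect_error(apply_constraint(s, mix, numeric(p)), "zero")
})

test_that("smooth-block draws satisfy the sum-to-zero identity", {
  d <- rand_dataset(60, seed = 65)
  d$covariates$u <- runif(60, -2, 2)
  spec <- cox_model_spec(d, smooths = smooth_spec("u", n_knots = 8))
  fit <- fit_cox(spec, k = 5, B = 500, seed = 7, theta_grid_points = 0)
  b <- spec$blocks[[1]]
  # sum over observed covariate values of gamma(u_i) is zero per draw
  g <- smooth_values(fit, "u")
  expect_lt(max(abs(rowSums(g))), 1e-8 * 60)
})

test_that("summaries obey the mixture laws and degenerate cases", {
  fit <- make_frailty_fit(B = 10000, seed = 8)
  mix <- attr(fit$samples, "corrected_mix")
  phi <- mix$phi
  means <- vapply(mix$components, function(c) c$mean,
                  numeric(fit$spec$dim_W))
  m_exact <- drop(means %*% phi)
  expect_equal(fit$summaries$mean_exact, m_exact, tolerance = 1e-10)
  # empirical vs mixture-exact agree within Monte-Carlo error
  se <- fit$summaries$sd_exact / sqrt(10000)
  expect_true(all(abs(fit$summaries$mean - fit$summaries$mean_exact) <
                  5 * se))
  # degenerate draws
  s0 <- structure(list(draws = matrix(2, 50, 1,
                                      dimnames = list(NULL, "w")),
                       component = rep(1L, 50)),
                  class = "posterior_samples")
  mix0 <- structure(list(components = list(list(mean = 2,
                                                chol_precision = matrix(1))),
                         phi = 1, spec = list(dim_W = 1)),
                    class = "cox_mixture_posterior")
  su <- summarize_samples(s0, mix0)
  expect_equal(su$sd, 0)
  expect_equal(su$lower, su$upper)
})

test_that("KS statistic matches enumeration of step functions", {
  expect_equal(ks_statistic(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ks_statistic(c(1, 2), c(10, 11)), 1)
  expect_equal(ks_statistic(c(1, 2), c(1.5, 2.5)), 0.5)
  # agreement with stats::ks.test on continuous samples
  set.seed(66)
  a <- rnorm(200); b <- rnorm(300, 0.3)
  expect_equal(ks_statistic(a, b),
               unname(stats::ks.test(a, b)$statistic), tolerance = 1e-12)
  expect_error(ks_statistic(numeric(0), 1), "empty")
})

test_that("exceedance probabilities are draw fractions", {
  dr <- cbind(log(c(2, 2, 2)), log(c(1, 2, 1)))
  expect_equal(exceedance(dr, 1.5), c(1, 1 / 3))
  expect_equal(exceedance(dr, 1e9), c(0, 0))
})

test_that("spatial prediction interpolates and matches block conditioning", {
  set.seed(67)
  coords <- matrix(runif(12), 6, 2)
  d <- survival_dataset(rexp(6) + 0.2, rep(1, 6), coords = coords)
  spec <- cox_model_spec(
    d, spatial = spatial_spec(
      prior_sigma = prior_exponential(median = 1, transform = "log"),
      prior_range = prior_exponential(median = 0.5, transform = "log")))
  fit <- fit_cox(spec, k = 3, B = 3000, seed = 9, theta_grid_points = 0)
  # prediction at an observed site reproduces the sampled values
  pr <- predict_spatial(fit, coords[2, , drop = FALSE], seed = 10)
  bidx <- spec$blocks[[1]]$idx
  expect_equal(drop(pr), fit$samples$draws[, bidx[2]], tolerance = 1e-6)
  # conditional mean/cov against brute-force joint conditioning, per theta
  snew <- matrix(c(0.5, 0.5), 1)
  kk <- fit$samples$component[1]
  th <- fit$mixture$components[[kk]]$theta
  sig <- exp(th[1]); rho <- exp(th[2])
  Call <- matern(as.matrix(dist(rbind(coords, snew))), sig, rho)
  Css <- Call[1:6, 1:6]; Cns <- Call[7, 1:6, drop = FALSE]
  mu_w <- drop(Cns %*% solve(Css))
  v_ref <- Call[7, 7] - drop(Cns %*% solve(Css, t(Cns)))
  rows <- which(fit$samples$component == kk)
  pr2 <- predict_spatial(fit, snew, seed = 11)[rows, 1]
  g <- fit$samples$draws[rows, bidx, drop = FALSE]
  resid <- pr2 - drop(g %*% mu_w)
  expect_lt(abs(mean(resid)), 5 * sqrt(v_ref / length(rows)))
  expect_equal(stats::var(resid), v_ref, tolerance = 0.15)
})

test_that("a quadratic likelihood makes the whole pipeline exact", {
  d <- rand_dataset(10, n_groups = 3, seed = 68)
  spec <- cox_model_spec(d, linear = "x")
  p <- spec$dim_W
  set.seed(69)
  m <- rnorm(p); A0 <- crossprod(matrix(rnorm(p * p), p)) + diag(p)
  fit <- fit_cox(spec, B = 20000, seed = 12,
                 loglik = quadratic_loglik(m, A0))
  Q <- assemble_Q(spec, numeric(0))
  mu_ref <- drop(solve(Q + A0, A0 %*% m))
  Sg_ref <- solve(Q + A0)
  expect_equal(fit$summaries$mean_exact, mu_ref, tolerance = 1e-6)
  expect_equal(fit$summaries$sd_exact, sqrt(diag(Sg_ref)), tolerance = 1e-6)
  expect_true(all(abs(colMeans(fit$samples$draws) - mu_ref) <
                  4 * sqrt(diag(Sg_ref) / 20000)))
})

test_that("credible intervals for beta attain nominal coverage", {
  # study-1 conditions: n = 60 groups, m = 5, sigma_xi = 1, beta = 0.2
  reps <- 200
  covered <- logical(reps)
  est <- numeric(reps)
  for (r in seq_len(reps)) {
    sim <- simulate_study1(m = 5, sigma_xi = 1, seed = 7000 + r)
    spec <- cox_model_spec(sim$data, linear = "x",
                           frailty_prior = prior_exponential(median = 1))
    fit <- fit_cox(spec, k = 15, B = 2000, seed = r,
                   theta_grid_points = 0)
    s <- fit$summaries["beta_x", ]
    covered[r] <- s$lower <= 0.2 && 0.2 <= s$upper
    est[r] <- s$mean
  }
  expect_gte(mean(covered), 0.95 - 0.031)
  expect_lte(mean(covered), 0.95 + 0.031)
  expect_lt(abs(mean(est) - 0.2), 0.05)
})
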