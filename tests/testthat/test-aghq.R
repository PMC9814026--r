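test_that("Gauss-Hermite rules are correct", {
  gh1 <- gauss_hermite(1)
  expect_equal(gh1$nodes, 0)
  expect_equal(gh1$weights, sqrt(pi))
  gh3 <- gauss_hermite(3)
  expect_equal(gh3$nodes, c(-sqrt(3 / 2), 0, sqrt(3 / 2)), tolerance = 1e-12)
  expect_equal(gh3$weights, c(sqrt(pi) / 6, 2 * sqrt(pi) / 3, sqrt(pi) / 6),
               tolerance = 1e-12)
  # exactness: integrate x^4 e^{-x^2} = 3 sqrt(pi)/4 with K = 3
  expect_equal(sum(gh3$weights * gh3$nodes^4), 3 * sqrt(pi) / 4,
               tolerance = 1e-12)
  expect_error(gauss_hermite(0), ">= 1")
})

test_that("the adapted rule integrates its own Gaussian to one for any K", {
  th <- c(0.4, -1.2)
  H <- matrix(c(2.5, 0.7, 0.7, 1.3), 2)
  S <- solve(H)
  dens <- function(x) {
    exp(-0.5 * colSums((t(x) - th) * (H %*% (t(x) - th)))) *
      sqrt(det(H)) / (2 * pi)
  }
  for (K in c(1, 2, 3, 7, 15)) {
    rule <- build_rule(th, H, K)
    expect_equal(sum(dens(rule$nodes) * rule$raw_weights), 1,
                 tolerance = 1e-12)
    expect_true(all(rule$raw_weights > 0))
    if (K %% 2 == 1) {
      expect_true(any(apply(rule$nodes, 1L, function(r) {
        isTRUE(all.equal(r, th, tolerance = 1e-12))
      })))
    }
  }
  # K = 1 degenerates to a single node at the mode
  r1 <- build_rule(th, H, 1)
  expect_equal(nrow(r1$nodes), 1L)
  expect_equal(drop(r1$nodes), th)
  expect_error(build_rule(th, H, 0), ">= 1")
})

test_that("mode finding recovers the analytic prior mode for event-free data", {
  d <- rand_dataset(10, n_groups = 3, seed = 51)
  spec <- cox_model_spec(d, frailty_prior = prior_exponential(median = 1))
  lam <- spec$theta_layout[[1]]$rate
  res <- find_mode_theta(spec, loglik = null_loglik(spec$dim_W))
  # stationary point of log(lam/2) - lam e^{-t/2} - t/2 is t = 2 log(lam)
  expect_equal(res$theta_hat, 2 * log(lam), tolerance = 1e-5)
})

test_that("mode finding matches a grid search on a quadratic toy", {
  d <- rand_dataset(14, n_groups = 4, seed = 52)
  spec <- cox_model_spec(d, frailty_prior = prior_exponential(median = 1))
  set.seed(53)
  m <- rnorm(spec$dim_W, 0, 0.8)
  A0 <- crossprod(matrix(rnorm(16), 4)) + diag(4)
  ql <- quadratic_loglik(m, A0)
  res <- find_mode_theta(spec, loglik = ql)
  grid <- seq(res$theta_hat - 0.5, res$theta_hat + 0.5, length.out = 2001)
  gv <- vapply(grid, function(th) {
    log_laplace_theta(spec, th, loglik = ql)$log_laplace
  }, numeric(1))
  expect_lt(abs(res$theta_hat - grid[which.max(gv)]), 1e-3)
})

test_that("mixture weights are normalized, invariant and hand-checkable", {
  rule <- build_rule(0, matrix(4), 3)
  lv <- c(-1.3, 0.2, -0.8)
  phi <- mixture_weights(rule, lv)
  expect_equal(sum(phi), 1)
  expect_true(all(phi >= 0))
  # hand computation
  w <- exp(lv) * rule$raw_weights
  expect_equal(as.numeric(phi), w / sum(w), tolerance = 1e-12)
  # invariance to additive constants
  phi2 <- mixture_weights(rule, lv + 123.4)
  expect_equal(as.numeric(phi), as.numeric(phi2), tolerance = 1e-12)
  # constant values with equal raw weights -> uniform
  rule1 <- build_rule(0, matrix(1), 1)
  expect_equal(as.numeric(mixture_weights(rule1, 0)), 1)
  expect_error(mixture_weights(rule, rep(-Inf, 3)), "vanish")
})

test_that("normalizing-constant estimate is stable in K on a frailty toy", {
  # a toy with genuine frailty variation, so the transformed-variance
  # posterior is well identified and close to Gaussian
  sim <- simulate_study1(m = 5, sigma_xi = 1, seed = 54)
  spec <- cox_model_spec(sim$data, linear = "x",
                         frailty_prior = prior_exponential(median = 1))
  ll <- pl_closure(spec, build_risk_sets(sim$data))
  res <- find_mode_theta(spec, loglik = ll)
  logZ <- vapply(c(7, 15), function(K) {
    rule <- build_rule(res$theta_hat, res$curvature, K)
    lv <- vapply(seq_len(nrow(rule$nodes)), function(k) {
      log_laplace_theta(spec, rule$nodes[k, ], loglik = ll,
                        start = res$W_hat)$log_laplace
    }, numeric(1))
    attr(mixture_weights(rule, lv), "log_Z")
  }, numeric(1))
  expect_lt(abs(logZ[1] - logZ[2]), 1e-3)
})

test_that("rule-based theta moments match fine-grid quadrature in 1-D", {
  sim <- simulate_study1(m = 5, sigma_xi = 1, seed = 55)
  spec <- cox_model_spec(sim$data, linear = "x",
                         frailty_prior = prior_exponential(median = 1))
  ll <- pl_closure(spec, build_risk_sets(sim$data))
  res <- find_mode_theta(spec, loglik = ll)
  rule <- build_rule(res$theta_hat, res$curvature, 15)
  lv <- vapply(seq_len(nrow(rule$nodes)), function(k) {
    log_laplace_theta(spec, rule$nodes[k, ], loglik = ll,
                      start = res$W_hat)$log_laplace
  }, numeric(1))
  phi <- mixture_weights(rule, lv)
  m_rule <- sum(phi * rule$nodes[, 1])
  sd_th <- sqrt(1 / res$curvature[1, 1])
  grid <- seq(res$theta_hat - 8 * sd_th, res$theta_hat + 8 * sd_th,
              length.out = 801)
  gv <- vapply(grid, function(th) {
    log_laplace_theta(spec, th, loglik = ll, start = res$W_hat)$log_laplace
  }, numeric(1))
  dens <- exp(gv - max(gv)); dens <- dens / sum(dens)
  m_grid <- sum(dens * grid)
  expect_lt(abs(m_rule - m_grid), 1e-3)
})
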