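# independent Cox-de Boor recursion for B-spline evaluation
cdb <- function(knots, i, k, x) {
  if (k == 1) {
    return(as.numeric(knots[i] <= x &
                      (x < knots[i + 1] |
                       (x == knots[i + 1] &
                        knots[i + 1] == knots[length(knots)]))))
  }
  w1 <- if (knots[i + k - 1] > knots[i]) {
    (x - knots[i]) / (knots[i + k - 1] - knots[i])
  } else 0
  w2 <- if (knots[i + k] > knots[i + 1]) {
    (knots[i + k] - x) / (knots[i + k] - knots[i + 1])
  } else 0
  w1 * cdb(knots, i, k - 1, x) + w2 * cdb(knots, i + 1, k - 1, x)
}

test_that("cubic B-spline basis has the right dimension and sums to one", {
  u <- seq(-2, 3, length.out = 40)
  bb <- build_bspline_basis(u, 50)
  expect_equal(ncol(bb$basis), 52)        # d = n_knots + 2
  expect_equal(rowSums(bb$basis), rep(1, 40), tolerance = 1e-12)
  bb2 <- build_bspline_basis(u, 7)
  expect_equal(ncol(bb2$basis), 9)
  expect_error(build_bspline_basis(rep(1, 5), 10), "constant")
  expect_error(build_bspline_basis(u, 3), "at least 4")
})

test_that("basis values match a direct Cox-de Boor recursion", {
  u <- c(0, 0.37, 0.5, 0.82, 1)
  bb <- build_bspline_basis(u, 4)
  d <- ncol(bb$basis)
  for (i in seq_len(d)) {
    ref <- vapply(u, function(x) cdb(bb$knots, i, 4, x), numeric(1))
    expect_equal(bb$basis[, i], ref, tolerance = 1e-12)
  }
})

test_that("penalty annihilates affine functions and is PSD of rank d-2", {
  u <- seq(0, 10, length.out = 30)
  bb <- build_bspline_basis(u, 8)
  S <- build_penalty(bb$knots)
  d <- ncol(bb$basis)
  # constant function: all-ones coefficients (partition of unity)
  expect_equal(max(abs(S %*% rep(1, d))), 0, tolerance = 1e-10)
  # linear function: coefficients are the Greville abscissae
  grev <- vapply(seq_len(d), function(i) mean(bb$knots[i + 1:3]), numeric(1))
  expect_equal(drop(bb$basis %*% grev), u, tolerance = 1e-10) # sanity
  expect_equal(max(abs(S %*% grev)), 0, tolerance = 1e-8)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-8))
  expect_equal(sum(ev < max(ev) * 1e-10), 2)  # rank d - 2
})

test_that("penalty entries agree with adaptive numerical quadrature", {
  u <- seq(0, 1, length.out = 10)
  bb <- build_bspline_basis(u, 5)
  S <- build_penalty(bb$knots)
  d <- ncol(bb$basis)
  phi2 <- function(x, i) {
    splines::splineDesign(bb$knots, x, ord = 4, derivs = rep(2L, length(x)),
                          outer.ok = TRUE)[, i]
  }
  for (i in c(1, 3, d)) {
    for (j in c(1, 4, d)) {
      ref <- stats::integrate(function(x) phi2(x, i) * phi2(x, j), 0, 1,
                              subdivisions = 400, rel.tol = 1e-10,
                              abs.tol = 1e-10)$value
      expect_equal(S[i, j], ref, tolerance = 1e-8)
    }
  }
})

test_that("Matern covariance has the right limits and shape", {
  expect_equal(matern(0, sigma = 2.5, rho = 3), 2.5^2)
  # practical-range convention: correlation sqrt(8)*K1(sqrt(8)) at h = rho
  thresh <- sqrt(8) * besselK(sqrt(8), 1)
  expect_equal(matern(3, sigma = 1, rho = 3), thresh)
  expect_lt(abs(thresh - 0.14), 0.005)
  # strictly decreasing, positive definite over random points
  h <- seq(0.01, 10, length.out = 50)
  v <- matern(h, 1, 2)
  expect_true(all(diff(v) < 0))
  set.seed(5)
  pts <- matrix(runif(10), 5, 2)
  C <- matern(as.matrix(dist(pts)), sigma = 1.3, rho = 0.7)
  expect_equal(C, t(C))
  expect_true(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) > 0)
  expect_error(matern(1, -1, 1), "sigma")
  expect_error(matern(1, 1, 0), "rho")
})

test_that("assemble_Q builds the correct block-diagonal precision", {
  # frailty-only with sigma_xi = 1: Q = I
  d <- rand_dataset(12, n_groups = 4, seed = 2)
  spec <- cox_model_spec(d, frailty_prior = prior_exponential(median = 1))
  Q <- assemble_Q(spec, theta = -2 * log(1))
  expect_equal(Q, diag(4))

  # smooth-only: smallest eigenvalue >= jitter
  d2 <- rand_dataset(25, seed = 3)
  d2$covariates$u <- seq(0, 1, length.out = 25)
  spec2 <- cox_model_spec(d2, smooths = smooth_spec("u", n_knots = 6))
  b <- spec2$blocks[[1]]
  Q2 <- assemble_Q(spec2, theta = 0.3)
  ev <- eigen(Q2, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), b$jitter * (1 - 1e-8))

  # spatial-only: Q is the inverse of the Matern covariance
  set.seed(9)
  coords <- matrix(runif(16), 8, 2)
  d3 <- survival_dataset(rexp(8) + 0.1, rep(1, 8), coords = coords)
  spec3 <- cox_model_spec(d3, spatial = spatial_spec())
  th <- c(log(1.2), log(0.6))
  Q3 <- assemble_Q(spec3, th)
  C <- matern(as.matrix(dist(coords)), 1.2, 0.6)
  expect_equal(unname(Q3 %*% C), diag(8), tolerance = 1e-8)

  expect_error(assemble_Q(spec, c(0, 1)), "length")
  expect_error(assemble_Q(spec, NaN), "finite")
})

test_that("Q is positive definite for randomized theta and models", {
  d <- rand_dataset(40, n_groups = 8, seed = 7)
  d$covariates$u <- runif(40)
  spec <- cox_model_spec(d, linear = "x",
                         smooths = smooth_spec("u", n_knots = 12),
                         frailty_prior = prior_exponential(median = 1))
  set.seed(11)
  for (r in 1:10) {
    th <- rnorm(2, 0, 2)
    ev <- eigen(assemble_Q(spec, th), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
})

test_that("eta_from_W is linear and matches a loop-based evaluation", {
  d <- rand_dataset(20, n_groups = 5, seed = 4)
  d$covariates$u <- runif(20)
  spec <- cox_model_spec(d, linear = "x",
                         smooths = smooth_spec("u", n_knots = 5),
                         frailty_prior = prior_exponential(median = 1))
  expect_equal(eta_from_W(spec, numeric(spec$dim_W)), rep(0, 20))
  set.seed(12)
  W1 <- rnorm(spec$dim_W); W2 <- rnorm(spec$dim_W)
  expect_equal(eta_from_W(spec, 2 * W1 - 3 * W2),
               2 * eta_from_W(spec, W1) - 3 * eta_from_W(spec, W2),
               tolerance = 1e-12)
  # explicit loop
  eta_loop <- numeric(20)
  sm <- spec$blocks[[1]]; ln <- spec$blocks[[2]]; fr <- spec$blocks[[3]]
  Bm <- build_bspline_basis(d$covariates$u, 5)$basis
  for (i in 1:20) {
    eta_loop[i] <- sum(Bm[i, ] * W1[sm$idx]) +
      d$covariates$x[i] * W1[ln$idx] + W1[fr$idx][d$group[i]]
  }
  expect_equal(eta_from_W(spec, W1), eta_loop, tolerance = 1e-12)

  # frailty-only indicator mapping
  df <- survival_dataset(c(1, 2, 3), c(1, 1, 1), group = c(1, 1, 2))
  specf <- cox_model_spec(df, frailty_prior = prior_exponential(median = 1))
  expect_equal(eta_from_W(specf, c(0.3, -0.7)), c(0.3, 0.3, -0.7))
})

test_that("intercept-like linear columns are rejected", {
  d <- rand_dataset(10, seed = 5)
  d$covariates$one <- 1
  expect_error(cox_model_spec(d, linear = c("x", "one")), "intercept")
})
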