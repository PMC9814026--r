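#' Gauss-Hermite nodes and weights
#'
#' Classical Gauss-Hermite rule for the weight \eqn{e^{-x^2}}, computed by
#' the Golub-Welsch eigen-decomposition of the Jacobi matrix of the
#' Hermite recurrence.  Exact for polynomials of degree \eqn{2n - 1}.
#'
#' @param n number of nodes (>= 1).
#' @return list with \code{nodes} (ascending) and \code{weights}.
#' @export
gauss_hermite <- function(n) {
  if (n < 1) stop("n must be >= 1")
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(n - 1L)
  b <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  nodes <- e$values[ord]
  # snap the central node of odd rules to exactly zero
  if (n %% 2L == 1L) nodes[(n + 1L) %/% 2L] <- 0
  list(nodes = nodes, weights = sqrt(pi) * e$vectors[1L, ord]^2)
}

#' Locate the mode of the Laplace-approximate hyperparameter posterior
#'
#' Quasi-Newton (BFGS) maximization of
#' \eqn{\log\tilde\pi_{LA}(\theta \mid y)} with a central finite-difference
#' gradient, followed by Newton polishing.  Inner optimizations are
#' warm-started from the previous evaluation's mode, which the strict
#' concavity of the inner objective makes safe.  The negative Hessian at
#' the optimum (finite differences of the gradient) is returned as the
#' curvature used to adapt the quadrature rule.
#'
#' @param spec a [cox_model_spec()].
#' @param loglik likelihood closure; defaults to the model's partial
#'   likelihood.
#' @param start starting value for \eqn{\theta}; defaults to the prior
#'   modes of the transformed hyperparameters.
#' @param fd_step central-difference step for the gradient (default 1e-4).
#' @param curv_step step for differencing the gradient into a Hessian
#'   (default 1e-3).
#' @param grad_tol required max-norm of the gradient at the optimum
#'   (default 1e-6).
#' @return list with \code{theta_hat}, \code{curvature} (negative Hessian,
#'   positive definite), \code{log_laplace_at_mode}, \code{W_hat} (inner
#'   mode at \eqn{\hat\theta}), \code{value_fn} (memoized evaluator of
#'   \eqn{\log\tilde\pi_{LA}} reusing warm starts).
#' @export
find_mode_theta <- function(spec, loglik = NULL, start = NULL,
                            fd_step = 1e-4, curv_step = 1e-3,
                            grad_tol = 1e-6) {
  if (is.null(loglik)) loglik <- pl_closure(spec, build_risk_sets(spec$data))
  dth <- spec$dim_theta
  if (dth == 0L) stop("model has no hyperparameters")
  if (is.null(start)) {
    start <- unname(vapply(spec$theta_layout, prior_theta_mode, numeric(1)))
  }
  start <- unname(start)
  env <- new.env()
  env$W <- NULL
  f <- function(theta) {
    r <- log_laplace_theta(spec, theta, loglik = loglik, start = env$W)
    env$W <- r$sol$W_hat
    r$log_laplace
  }
  grad_f <- function(theta) {
    vapply(seq_len(dth), function(j) {
      e <- numeric(dth); e[j] <- fd_step
      (f(theta + e) - f(theta - e)) / (2 * fd_step)
    }, numeric(1))
  }
  opt <- stats::optim(start, fn = function(th) -f(th),
                      gr = function(th) -grad_f(th),
                      method = "BFGS",
                      control = list(reltol = 1e-12, maxit = 200))
  theta <- opt$par
  # Newton polish on the theta scale
  for (polish in 1:10) {
    g <- grad_f(theta)
    if (max(abs(g)) <= grad_tol) break
    H <- fd_hessian(grad_f, theta, curv_step)
    step <- tryCatch(solve(H, -g), error = function(e) NULL)
    if (is.null(step)) break
    cand <- theta + step
    if (f(cand) >= f(theta)) theta <- cand else break
  }
  curv <- -fd_hessian(grad_f, theta, curv_step)
  curv <- (curv + t(curv)) / 2
  ev <- eigen(curv, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("curvature at the located optimum is not positive definite; ",
         "try a different start or reparameterize")
  }
  r <- log_laplace_theta(spec, theta, loglik = loglik, start = env$W)
  list(theta_hat = theta, curvature = curv,
       log_laplace_at_mode = r$log_laplace, W_hat = r$sol$W_hat,
       value_fn = f)
}

# central-difference Jacobian of a gradient function (Hessian of f)
fd_hessian <- function(grad_f, theta, h) {
  d <- length(theta)
  H <- matrix(0, d, d)
  for (j in seq_len(d)) {
    e <- numeric(d); e[j] <- h
    H[, j] <- (grad_f(theta + e) - grad_f(theta - e)) / (2 * h)
  }
  (H + t(H)) / 2
}

#' Build an adaptive Gauss-Hermite quadrature rule
#'
#' Product Gauss-Hermite rule recentred at the mode \eqn{\hat\theta} and
#' rescaled by the local curvature: with \eqn{L L^T = \mathrm{curv}^{-1}},
#' nodes are \eqn{\theta_k = \hat\theta + \sqrt{2}\, L z_k} and raw
#' weights \eqn{\delta_k = 2^{d/2} |L|\, \omega_k e^{\|z_k\|^2}}, so that
#' \eqn{\sum_k f(\theta_k)\,\delta_k} approximates \eqn{\int f}.  The rule
#' integrates the adapted Gaussian exactly for any K, and K = 1
#' degenerates to a pure Laplace approximation with the single node
#' \eqn{\hat\theta}.
#'
#' @param theta_hat mode vector.
#' @param curvature negative Hessian of \eqn{\log\tilde\pi_{LA}} at the
#'   mode (positive definite).
#' @param k_per_dim nodes per hyperparameter dimension (>= 1).
#' @return object of class \code{aghq_rule}: \code{nodes} (K_total x d
#'   matrix), \code{raw_weights}, \code{mode}, \code{curvature},
#'   \code{scale_L}, \code{k_per_dim}, \code{z} (standardized nodes).
#' @export
build_rule <- function(theta_hat, curvature, k_per_dim) {
  if (k_per_dim < 1) stop("k_per_dim must be >= 1")
  d <- length(theta_hat)
  curvature <- as.matrix(curvature)
  stopifnot(nrow(curvature) == d)
  Sig <- solve(curvature)
  Sig <- (Sig + t(Sig)) / 2
  L <- t(chol(Sig))                  # lower, L L^T = curvature^{-1}
  gh <- gauss_hermite(k_per_dim)
  grids <- rep(list(seq_len(k_per_dim)), d)
  idx <- as.matrix(expand.grid(grids))
  Z <- matrix(gh$nodes[idx], ncol = d)
  logw <- matrix(log(gh$weights)[idx], ncol = d)
  nodes <- t(theta_hat + sqrt(2) * (L %*% t(Z)))
  raw <- exp(rowSums(logw) + rowSums(Z^2)) * 2^(d / 2) * prod(diag(L))
  structure(
    list(nodes = nodes, raw_weights = raw, mode = theta_hat,
         curvature = curvature, scale_L = L, k_per_dim = k_per_dim,
         z = Z),
    class = "aghq_rule")
}

#' Normalized mixture weights from log integrand values
#'
#' \eqn{\phi_k \propto \exp\{\log\tilde\pi_{LA}(\theta_k)\}\,\delta_k},
#' normalized to sum to one with log-sum-exp stabilization.  The log of
#' the unnormalized sum (the quadrature estimate of the normalizing
#' constant of \eqn{\tilde\pi_{LA}}) is attached as attribute
#' \code{"log_Z"}.
#'
#' @param rule an [build_rule()] quadrature rule.
#' @param log_values \eqn{\log\tilde\pi_{LA}} at the rule's nodes.
#' @return numeric weight vector summing to one.
#' @export
mixture_weights <- function(rule, log_values) {
  if (length(log_values) != length(rule$raw_weights)) {
    stop("log_values length does not match the rule")
  }
  lw <- log_values + log(rule$raw_weights)
  if (all(!is.finite(lw))) stop("all mixture weights vanish")
  m <- max(lw[is.finite(lw)])
  w <- exp(lw - m)
  w[!is.finite(w)] <- 0
  phi <- w / sum(w)
  attr(phi, "log_Z") <- m + log(sum(w))
  phi
}
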