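#' Likelihood closure for the partial likelihood
#'
#' Packages the partial likelihood of a model as a function
#' \code{f(W, hessian = TRUE)} returning \code{value}, \code{gradient} and
#' \code{neg_hessian} with respect to the latent vector.  The Laplace and
#' quadrature machinery is written against this interface so that a
#' different log-likelihood (e.g. an exact quadratic one, for which the
#' Laplace approximation is exact) can be substituted in tests and
#' validation.
#'
#' @param spec a [cox_model_spec()].
#' @param risk a [build_risk_sets()] index for the same data.
#' @return a function of \code{(W, hessian)}.
#' @export
pl_closure <- function(spec, risk) {
  force(spec); force(risk)
  function(W, hessian = TRUE) pl_derivatives(spec, W, risk, hessian = hessian)
}

#' Quadratic (Gaussian) pseudo-likelihood closure
#'
#' \eqn{\ell(W) = -\tfrac12 (W - m)^T A (W - m)} plus a constant.  With a
#' Gaussian prior this makes every approximation in the pipeline exact,
#' giving a closed-form oracle for end-to-end validation: posterior
#' \eqn{N\big((Q + A)^{-1} A m,\ (Q + A)^{-1}\big)}.
#'
#' @param m mean vector.
#' @param A symmetric positive semi-definite curvature matrix.
#' @param const additive constant (the true Gaussian log-normalizing
#'   constant, if the pseudo-likelihood is to integrate to one).
#' @return a likelihood closure as in [pl_closure()].
#' @export
quadratic_loglik <- function(m, A, const = 0) {
  force(m); force(A); force(const)
  function(W, hessian = TRUE) {
    r <- W - m
    g <- -drop(A %*% r)
    list(value = const - 0.5 * sum(r * (A %*% r)), gradient = g,
         neg_hessian = if (hessian) A else NULL)
  }
}

#' Inner optimization: conditional posterior mode of the latent field
#'
#' Maximizes the strictly concave objective
#' \eqn{-\tfrac12 W^T Q_\theta W + \ell(W)} by Newton's method with
#' step-halving, returning the conditional mode \eqn{\hat W_\theta}, the
#' curvature \eqn{H_\theta = Q_\theta - \nabla^2 \ell} at the mode (kept
#' with its Cholesky factor for reuse in sampling), and the objective
#' pieces needed by the Laplace approximation.
#'
#' @param Q prior precision matrix (positive definite).
#' @param loglik a likelihood closure ([pl_closure()]).
#' @param start starting latent vector (default zero).
#' @param tol convergence tolerance on the max-norm gradient
#'   (default 1e-8).
#' @param max_iter maximum Newton iterations (default 50).
#' @return list of class \code{inner_solution}: \code{W_hat},
#'   \code{hessian} (\eqn{H_\theta}), \code{chol_H} (upper Cholesky
#'   factor), \code{loglik_value}, \code{quad} (\eqn{\hat W^T Q \hat W}),
#'   \code{converged}, \code{iterations}, \code{grad_norm}.
#' @export
optimize_W <- function(Q, loglik, start = NULL, tol = 1e-8, max_iter = 50L) {
  d <- nrow(Q)
  W <- if (is.null(start)) numeric(d) else start
  if (length(W) != d) stop("start has wrong length")
  obj_at <- function(W, lk) -0.5 * sum(W * (Q %*% W)) + lk
  lk <- loglik(W, hessian = TRUE)
  obj <- obj_at(W, lk$value)
  converged <- FALSE
  it <- 0L
  grad <- lk$gradient - drop(Q %*% W)
  repeat {
    if (max(abs(grad)) <= tol) { converged <- TRUE; break }
    if (it >= max_iter) break
    it <- it + 1L
    H <- Q + lk$neg_hessian
    R <- tryCatch(chol(H), error = function(e) NULL)
    if (is.null(R)) {
      # fall back: inflate the (tiny or zero) negative eigenvalues
      H <- H + diag(1e-8 + max(0, -min(eigen(H, symmetric = TRUE,
                                             only.values = TRUE)$values)),
                    d)
      R <- chol(H)
    }
    step <- backsolve(R, forwardsolve(t(R), grad))
    alpha <- 1
    for (h in 0:30) {
      W_new <- W + alpha * step
      lk_new <- loglik(W_new, hessian = FALSE)
      obj_new <- obj_at(W_new, lk_new$value)
      if (is.finite(obj_new) && obj_new >= obj - 1e-12) break
      alpha <- alpha / 2
    }
    W <- W_new
    lk <- loglik(W, hessian = TRUE)
    obj <- obj_at(W, lk$value)
    grad <- lk$gradient - drop(Q %*% W)
  }
  H <- Q + lk$neg_hessian
  H <- (H + t(H)) / 2
  R <- tryCatch(chol(H), error = function(e) {
    stop("curvature at the inner mode is not positive definite")
  })
  structure(
    list(W_hat = W, hessian = H, chol_H = R,
         loglik_value = lk$value, quad = sum(W * (Q %*% W)),
         converged = converged, iterations = it,
         grad_norm = max(abs(grad))),
    class = "inner_solution")
}

#' Gaussian approximation to the conditional posterior
#'
#' Second-order Taylor expansion of \eqn{\log\pi(W \mid \theta, y)} about
#' its mode: mean \eqn{\hat W_\theta}, precision \eqn{H_\theta(\hat
#' W_\theta)}.  These are the mixture components of the approximate
#' posterior of \eqn{W}.
#'
#' @param sol an [optimize_W()] solution.
#' @return list with \code{mean}, \code{precision}, \code{chol_precision}.
#' @export
gaussian_approx <- function(sol) {
  stopifnot(inherits(sol, "inner_solution"))
  if (!sol$converged) {
    warning("inner optimization did not converge (grad norm ",
            signif(sol$grad_norm, 3), ")")
  }
  list(mean = sol$W_hat, precision = sol$hessian,
       chol_precision = sol$chol_H)
}

#' Log Laplace approximation to the hyperparameter posterior
#'
#' Tierney-Kadane approximation, up to a constant:
#' \deqn{\log\tilde\pi_{LA}(\theta \mid y) = \log\pi(\theta) +
#'   \tfrac12\log|Q_\theta| - \tfrac12\log|H_\theta(\hat W_\theta)| -
#'   \tfrac12 \hat W_\theta^T Q_\theta \hat W_\theta +
#'   \ell(\hat W_\theta).}
#' Determinants come from triangular (Cholesky) factors.  For event-free
#' data (\eqn{\ell \equiv 0}) everything cancels and the function reduces
#' to the prior.
#'
#' @param spec a [cox_model_spec()].
#' @param theta hyperparameter vector.
#' @param loglik likelihood closure; defaults to the partial likelihood of
#'   \code{spec} with risk sets built from its data.
#' @param start warm start for the inner optimization.
#' @param tol,max_iter passed to [optimize_W()].
#' @return list with \code{log_laplace} (unnormalized), \code{sol} (the
#'   inner solution).
#' @export
log_laplace_theta <- function(spec, theta, loglik = NULL, start = NULL,
                              tol = 1e-8, max_iter = 50L) {
  if (is.null(loglik)) {
    loglik <- pl_closure(spec, build_risk_sets(spec$data))
  }
  Q <- assemble_Q(spec, theta)
  sol <- optimize_W(Q, loglik, start = start, tol = tol,
                    max_iter = max_iter)
  ld_Q <- logdet_Q(spec, theta)
  ld_H <- 2 * sum(log(diag(sol$chol_H)))
  val <- log_prior_theta(spec$theta_layout, theta) +
    0.5 * ld_Q - 0.5 * ld_H - 0.5 * sol$quad + sol$loglik_value
  list(log_laplace = val, sol = sol)
}
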