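#' Exponential prior on a standard-deviation or range parameter
#'
#' Variance-type hyperparameters are given exponential priors on their
#' natural scale (standard deviation \eqn{\sigma}, or practical range
#' \eqn{\rho} for spatial terms), the simplest penalized-complexity-type
#' prior: it shrinks toward the base model \eqn{\sigma = 0} at a constant
#' exponential rate.  The prior is specified either through its median or
#' through a tail probability \eqn{P(\sigma > q) = p}.
#'
#' Internally the model works on a transformed scale
#' (\eqn{\theta = -2\log\sigma} for smooth and frailty variances,
#' \eqn{\theta = \log\sigma} or \eqn{\log\rho} for Matern parameters), and
#' the density carries the change-of-variables Jacobian.
#'
#' @param median prior median on the natural scale.
#' @param q,p alternative tail specification: \eqn{P(\sigma > q) = p}.
#' @param transform one of \code{"minus2log"} (\eqn{\theta = -2\log\sigma}),
#'   \code{"log"} (\eqn{\theta = \log\sigma}).
#' @return An object of class \code{prior_spec} with fields \code{family},
#'   \code{rate}, \code{transform}.
#' @export
prior_exponential <- function(median = NULL, q = NULL, p = NULL,
                              transform = c("minus2log", "log")) {
  transform <- match.arg(transform)
  if (!is.null(median)) {
    rate <- rate_from_median(median)
  } else if (!is.null(q) && !is.null(p)) {
    rate <- rate_from_tail(q, p)
  } else {
    stop("specify either `median` or both `q` and `p`")
  }
  structure(list(family = "exponential", rate = rate, transform = transform),
            class = "prior_spec")
}

#' Exponential rate from a median
#'
#' Solves \eqn{P(\sigma > m) = 1/2} for the rate of an exponential
#' distribution: \eqn{\lambda = \log(2)/m}.
#'
#' @param median positive prior median.
#' @return the rate \eqn{\lambda}.
#' @export
rate_from_median <- function(median) {
  if (!is.numeric(median) || median <= 0) stop("median must be positive")
  log(2) / median
}

#' Exponential rate from a tail probability
#'
#' Solves \eqn{P(\sigma > q) = p}: \eqn{\lambda = -\log(p)/q}.
#'
#' @param q positive quantile.
#' @param tail_prob tail probability in (0, 1).
#' @return the rate \eqn{\lambda}.
#' @export
rate_from_tail <- function(q, tail_prob) {
  if (!is.numeric(q) || q <= 0) stop("quantile must be positive")
  if (!is.numeric(tail_prob) || tail_prob <= 0 || tail_prob >= 1) {
    stop("tail probability must be in (0, 1)")
  }
  -log(tail_prob) / q
}

# log prior density of one theta coordinate under its prior_spec,
# including the Jacobian of the sigma -> theta transformation.
log_prior_one <- function(spec, theta) {
  lam <- spec$rate
  switch(spec$transform,
    minus2log = {
      # sigma = exp(-theta/2), |dsigma/dtheta| = sigma/2
      log(lam / 2) - lam * exp(-theta / 2) - theta / 2
    },
    log = {
      # sigma = exp(theta), |dsigma/dtheta| = sigma
      log(lam) - lam * exp(theta) + theta
    },
    stop("unknown transform: ", spec$transform))
}

#' Log prior density of the variance-parameter vector
#'
#' Sum of independent transformed exponential log densities, one per
#' \eqn{\theta} coordinate, each with its change-of-variables Jacobian.
#' For \eqn{\theta = -2\log\sigma} with rate \eqn{\lambda} this is
#' \eqn{\log(\lambda/2) - \lambda e^{-\theta/2} - \theta/2}.
#'
#' @param specs list of \code{prior_spec} objects, one per coordinate.
#' @param theta numeric vector, same length.
#' @return scalar log density.
#' @export
log_prior_theta <- function(specs, theta) {
  if (length(specs) != length(theta)) stop("specs and theta lengths differ")
  if (length(theta) == 0L) return(0)
  if (any(!is.finite(theta))) stop("non-finite theta")
  sum(vapply(seq_along(theta),
             function(i) log_prior_one(specs[[i]], theta[i]), numeric(1)))
}

# Derivative of log_prior_one wrt theta (used by the MCMC oracle).
dlog_prior_one <- function(spec, theta) {
  lam <- spec$rate
  switch(spec$transform,
    minus2log = lam / 2 * exp(-theta / 2) - 1 / 2,
    log = -lam * exp(theta) + 1,
    stop("unknown transform: ", spec$transform))
}

# Exact mode of the transformed prior (stationary point of log_prior_one).
prior_theta_mode <- function(spec) {
  lam <- spec$rate
  switch(spec$transform,
    minus2log = 2 * log(lam),   # lam/2 e^{-t/2} = 1/2  =>  t = 2 log lam
    log = -log(lam),            # lam e^t = 1           =>  t = -log lam
    stop("unknown transform: ", spec$transform))
}

# Draw from the prior on the theta scale (used for initialization).
prior_theta_draw <- function(spec, n = 1L) {
  sig <- stats::rexp(n, rate = spec$rate)
  switch(spec$transform,
    minus2log = -2 * log(sig),
    log = log(sig))
}
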