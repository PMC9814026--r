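#' Exact joint log posterior of (W, theta) and its gradient
#'
#' Builds the unnormalized log joint
#' \deqn{\log\pi(W, \theta \mid y) = \log\pi(\theta) +
#'   \tfrac12\log|Q_\theta| - \tfrac12 W^T Q_\theta W + \ell(\eta(W)),}
#' with \eqn{\theta} on its unconstrained transformed scale (Jacobians in
#' the prior).  The gradient in \eqn{W} is analytic; the gradient in
#' \eqn{\theta} is analytic for frailty and smooth blocks (their
#' precisions are linear in \eqn{e^\theta}) and central-finite-difference
#' for Matern spatial blocks.  This is the target of the MCMC oracle used
#' to validate the approximation.
#'
#' @param spec a [cox_model_spec()].
#' @param risk optional risk-set index (built from the data when omitted).
#' @param loglik optional likelihood closure overriding the partial
#'   likelihood.
#' @return list with \code{lp(x)}, \code{grad(x)}, \code{dim},
#'   \code{dim_W}, \code{names}; \code{x = c(W, theta)}.
#' @export
joint_posterior <- function(spec, risk = NULL, loglik = NULL) {
  if (is.null(risk)) risk <- build_risk_sets(spec$data)
  if (is.null(loglik)) loglik <- pl_closure(spec, risk)
  dW <- spec$dim_W
  dth <- spec$dim_theta
  lp <- function(x) {
    W <- x[seq_len(dW)]
    theta <- x[dW + seq_len(dth)]
    Qb <- Q_block_list(spec, theta)
    quad <- 0; ld <- 0
    for (i in seq_along(spec$blocks)) {
      wi <- W[spec$blocks[[i]]$idx]
      quad <- quad + sum(wi * (Qb[[i]] %*% wi))
      ld <- ld + 2 * sum(log(diag(chol(Qb[[i]]))))
    }
    log_prior_theta(spec$theta_layout, theta) + 0.5 * ld - 0.5 * quad +
      loglik(W, hessian = FALSE)$value
  }
  grad <- function(x) {
    W <- x[seq_len(dW)]
    theta <- x[dW + seq_len(dth)]
    Qb <- Q_block_list(spec, theta)
    gW <- loglik(W, hessian = FALSE)$gradient
    gth <- numeric(dth)
    for (i in seq_along(spec$blocks)) {
      b <- spec$blocks[[i]]
      wi <- W[b$idx]
      gW[b$idx] <- gW[b$idx] - drop(Qb[[i]] %*% wi)
      if (b$type == "frailty") {
        q <- b$theta_idx
        et <- exp(theta[q])
        gth[q] <- gth[q] + 0.5 * b$dim - 0.5 * et * sum(wi^2)
      } else if (b$type == "smooth") {
        q <- b$theta_idx
        et <- exp(theta[q])
        tr <- sum(diag(solve(Qb[[i]], b$penalty))) * et
        gth[q] <- gth[q] + 0.5 * tr - 0.5 * et * sum(wi * (b$penalty %*% wi))
      } else if (b$type == "spatial") {
        # FD on 0.5 log|Q_b| - 0.5 w' Q_b w in the two Matern parameters
        fb <- function(th2) {
          sig <- exp(th2[1L]); rho <- exp(th2[2L])
          C <- matern(b$distances, sig, rho)
          R <- chol(C)
          v <- backsolve(R, forwardsolve(t(R), wi))
          -sum(log(diag(R))) - 0.5 * sum(wi * v)
        }
        th2 <- theta[b$theta_idx]
        h <- 1e-5
        for (j in 1:2) {
          e <- c(0, 0); e[j] <- h
          gth[b$theta_idx[j]] <- gth[b$theta_idx[j]] +
            (fb(th2 + e) - fb(th2 - e)) / (2 * h)
        }
      }
    }
    for (q in seq_len(dth)) {
      gth[q] <- gth[q] + dlog_prior_one(spec$theta_layout[[q]], theta[q])
    }
    c(gW, gth)
  }
  list(lp = lp, grad = grad, dim = dW + dth, dim_W = dW,
       names = c(spec$coef_names, names(spec$theta_layout)))
}

# Non-centered joint posterior used by the HMC oracle.
#
# Smooth blocks are reparameterized exactly through the eigen-decomposition
# of their penalty: with P = U diag(d) U' and Q(theta) = e^theta P + jI,
# the block is W = U S(theta) V, S_i = (e^theta d_i + j)^{-1/2}, V ~ N(0, I).
# Frailty blocks use W = e^{-theta/2} V.  This removes the prior's
# theta-dependent scale from the latent coordinates (the funnel that makes
# centered HMC mix slowly in the smoothing parameter) while targeting the
# identical posterior.  Spatial blocks stay centered (their covariance is
# not a simple scale family in both parameters); linear blocks have no
# hyperparameter.
joint_posterior_nc <- function(spec, risk = NULL, loglik = NULL) {
  if (is.null(risk)) risk <- build_risk_sets(spec$data)
  if (is.null(loglik)) loglik <- pl_closure(spec, risk)
  dW <- spec$dim_W
  dth <- spec$dim_theta
  eig <- lapply(spec$blocks, function(b) {
    if (b$type == "smooth") {
      e <- eigen(b$penalty, symmetric = TRUE)
      list(U = e$vectors, d = pmax(e$values, 0), j = b$jitter)
    } else NULL
  })
  W_from_x <- function(x) {
    W <- x[seq_len(dW)]
    theta <- x[dW + seq_len(dth)]
    for (i in seq_along(spec$blocks)) {
      b <- spec$blocks[[i]]
      if (b$type == "smooth") {
        s <- 1 / sqrt(exp(theta[b$theta_idx]) * eig[[i]]$d + eig[[i]]$j)
        W[b$idx] <- drop(eig[[i]]$U %*% (s * crossprod(eig[[i]]$U, W[b$idx])))
      } else if (b$type == "frailty") {
        W[b$idx] <- exp(-theta[b$theta_idx] / 2) * W[b$idx]
      }
    }
    W
  }
  lp <- function(x) {
    V <- x[seq_len(dW)]
    theta <- x[dW + seq_len(dth)]
    W <- W_from_x(x)
    out <- log_prior_theta(spec$theta_layout, theta) +
      loglik(W, hessian = FALSE)$value
    for (i in seq_along(spec$blocks)) {
      b <- spec$blocks[[i]]
      vi <- V[b$idx]
      if (b$type %in% c("smooth", "frailty", "linear")) {
        pv <- if (b$type == "linear") b$prior_variance else 1
        out <- out - 0.5 * sum(vi^2) / pv
      } else {                        # spatial: centered
        sig <- exp(theta[b$theta_idx[1L]])
        rho <- exp(theta[b$theta_idx[2L]])
        C <- matern(b$distances, sig, rho)
        R <- chol(C)
        z <- forwardsolve(t(R), vi)
        out <- out - sum(log(diag(R))) - 0.5 * sum(z^2)
      }
    }
    out
  }
  grad <- function(x) {
    V <- x[seq_len(dW)]
    theta <- x[dW + seq_len(dth)]
    W <- W_from_x(x)
    gW <- loglik(W, hessian = FALSE)$gradient
    gV <- numeric(dW)
    gth <- numeric(dth)
    for (i in seq_along(spec$blocks)) {
      b <- spec$blocks[[i]]
      vi <- V[b$idx]
      gwb <- gW[b$idx]
      if (b$type == "smooth") {
        q <- b$theta_idx
        et <- exp(theta[q])
        lam <- et * eig[[i]]$d + eig[[i]]$j
        s <- 1 / sqrt(lam)
        a <- drop(crossprod(eig[[i]]$U, vi))
        ug <- drop(crossprod(eig[[i]]$U, gwb))
        gV[b$idx] <- drop(eig[[i]]$U %*% (s * ug)) - vi
        ds <- -0.5 * et * eig[[i]]$d * lam^(-1.5)
        gth[q] <- gth[q] + sum(ug * ds * a)
      } else if (b$type == "frailty") {
        q <- b$theta_idx
        sc <- exp(-theta[q] / 2)
        gV[b$idx] <- sc * gwb - vi
        gth[q] <- gth[q] - 0.5 * sum(gwb * (sc * vi))
      } else if (b$type == "linear") {
        gV[b$idx] <- gwb - vi / b$prior_variance
      } else {                        # spatial, centered
        fb <- function(th2) {
          sig <- exp(th2[1L]); rho <- exp(th2[2L])
          C <- matern(b$distances, sig, rho)
          R <- chol(C)
          z <- forwardsolve(t(R), vi)
          -sum(log(diag(R))) - 0.5 * sum(z^2)
        }
        th2 <- theta[b$theta_idx]
        h <- 1e-5
        for (j in 1:2) {
          e <- c(0, 0); e[j] <- h
          gth[b$theta_idx[j]] <- gth[b$theta_idx[j]] +
            (fb(th2 + e) - fb(th2 - e)) / (2 * h)
        }
        sig <- exp(th2[1L]); rho <- exp(th2[2L])
        C <- matern(b$distances, sig, rho)
        R <- chol(C)
        gV[b$idx] <- gwb - backsolve(R, forwardsolve(t(R), vi))
      }
    }
    for (q in seq_len(dth)) {
      gth[q] <- gth[q] + dlog_prior_one(spec$theta_layout[[q]], theta[q])
    }
    c(gV, gth)
  }
  list(lp = lp, grad = grad, W_from_x = W_from_x, dim = dW + dth,
       dim_W = dW, names = c(spec$coef_names, names(spec$theta_layout)))
}

#' Hamiltonian Monte Carlo sampler
#'
#' Plain HMC with leapfrog integration, dual-averaging step-size
#' adaptation toward a target acceptance rate during warmup, and a
#' diagonal mass matrix estimated from mid-warmup draws.  The trajectory
#' length is jittered to avoid resonance.  Generic engine behind
#' [run_mcmc()]; also usable on any differentiable log density.
#'
#' @param lp log-density function.
#' @param grad gradient function.
#' @param init initial state vector.
#' @param iterations total iterations (including warmup).
#' @param warmup number of warmup iterations (adapted, then discarded).
#' @param leapfrog maximum leapfrog steps per iteration (default 12).
#' @param target_accept dual-averaging target (default 0.8).
#' @param seed RNG seed.
#' @return list with \code{draws} ((iterations - warmup) x dim),
#'   \code{accept_rate}, \code{step_size}, \code{divergences}.
#' @export
hmc_sample <- function(lp, grad, init, iterations, warmup,
                       leapfrog = 12L, target_accept = 0.8, seed = 1) {
  stopifnot(iterations > warmup)
  set.seed(seed)
  d <- length(init)
  x <- init
  lx <- lp(x)
  if (!is.finite(lx)) stop("log density not finite at init")
  # metric: momenta p ~ N(0, Sigma^{-1}); identity until mid-warmup, then a
  # shrunk dense covariance estimate (whitens correlated directions)
  Sig_R <- diag(1, d)        # upper chol factor R, Sigma = R' R
  Sig <- diag(1, d)
  eps <- 0.1
  # dual averaging state
  mu <- log(10 * eps); log_eps_bar <- log(eps); Hbar <- 0
  gam <- 0.05; t0 <- 10; kap <- 0.75; da_t <- 0
  m1 <- floor(warmup * 0.4); m2 <- floor(warmup * 0.85)
  acc_buf <- numeric(0)
  win <- matrix(0, max(m2 - m1, 1L), d)
  wrow <- 0L
  kept <- matrix(0, iterations - warmup, d)
  n_div <- 0L
  acc_sum <- 0
  kin <- function(p) { v <- drop(Sig_R %*% p); 0.5 * sum(v^2) }
  for (it in seq_len(iterations)) {
    p <- drop(backsolve(Sig_R, stats::rnorm(d)))
    x_new <- x
    g <- grad(x_new)
    p_new <- p
    L <- sample.int(leapfrog, 1L)
    diverged <- FALSE
    for (s in seq_len(L)) {
      p_new <- p_new + 0.5 * eps * g
      x_new <- x_new + eps * drop(Sig %*% p_new)
      g <- tryCatch(grad(x_new), error = function(e) NULL)
      if (is.null(g) || any(!is.finite(g))) { diverged <- TRUE; break }
      p_new <- p_new + 0.5 * eps * g
    }
    if (diverged) {
      a <- 0
    } else {
      l_new <- tryCatch(lp(x_new), error = function(e) -Inf)
      dH <- (l_new - kin(p_new)) - (lx - kin(p))
      if (!is.finite(dH)) { a <- 0; diverged <- TRUE }
      else a <- min(1, exp(dH))
      if (!diverged && stats::runif(1) < a) { x <- x_new; lx <- l_new }
    }
    if (diverged && it > warmup) n_div <- n_div + 1L
    if (it <= warmup) {
      # dual averaging
      da_t <- da_t + 1
      Hbar <- (1 - 1 / (da_t + t0)) * Hbar +
        (target_accept - a) / (da_t + t0)
      log_eps <- mu - sqrt(da_t) / gam * Hbar
      w <- da_t^(-kap)
      log_eps_bar <- w * log_eps + (1 - w) * log_eps_bar
      eps <- exp(log_eps)
      if (it > m1 && it <= m2) {
        wrow <- wrow + 1L
        win[wrow, ] <- x
      }
      if (it == m2 && wrow > 10L) {
        Wn <- win[seq_len(wrow), , drop = FALSE]
        Cv <- stats::cov(Wn)
        # shrink toward the diagonal for stability at modest window sizes
        lamb <- wrow / (wrow + 5)
        Cv <- lamb * Cv + (1 - lamb) * diag(pmax(diag(Cv), 1e-8), d)
        diag(Cv) <- diag(Cv) + 1e-8
        Sig <- Cv
        Sig_R <- chol(Sig)
        # restart step-size adaptation under the new metric
        eps <- max(exp(log_eps_bar), 0.05)
        mu <- log(10 * eps); Hbar <- 0; da_t <- 0
        log_eps_bar <- log(eps)
      }
      if (it == warmup) eps <- exp(log_eps_bar)
    } else {
      kept[it - warmup, ] <- x
      acc_sum <- acc_sum + a
    }
  }
  list(draws = kept, accept_rate = acc_sum / (iterations - warmup),
       step_size = eps, divergences = n_div)
}

#' Run the MCMC oracle on the exact joint posterior
#'
#' Multiple independent HMC chains targeting
#' \eqn{\pi(W, \theta \mid y)} under the same partial likelihood and
#' priors as the approximation, with split-\eqn{\hat R} and effective
#' sample size diagnostics.  A run is suitable as an oracle when all
#' \eqn{\hat R < 1.01}.
#'
#' @param spec a [cox_model_spec()].
#' @param chains number of chains (>= 2 for diagnostics).
#' @param iterations per-chain iterations including warmup.
#' @param warmup warmup iterations per chain.
#' @param seed master seed; chain c uses \code{seed * 1000 + c}.
#' @param leapfrog,target_accept passed to [hmc_sample()].
#' @param init optional initial state; default: inner mode at the prior
#'   modes of \eqn{\theta}, with per-chain overdispersion.
#' @return object of class \code{mcmc_run}: \code{draws} (stacked
#'   post-warmup draws), \code{chain} (chain index per row),
#'   \code{names}, \code{diagnostics} (rhat, ess per parameter),
#'   \code{ok} (all rhat < 1.01), \code{divergences}.
#' @export
run_mcmc <- function(spec, chains = 4, iterations = 10000, warmup = 5000,
                     seed = 1, leapfrog = 12L, target_accept = 0.8,
                     init = NULL) {
  stopifnot(chains >= 2, iterations > warmup)
  jp <- joint_posterior_nc(spec)
  if (is.null(init)) {
    th0 <- vapply(spec$theta_layout, prior_theta_mode, numeric(1))
    init <- c(numeric(spec$dim_W), th0)
  }
  kept <- iterations - warmup
  draws <- matrix(0, chains * kept, jp$dim)
  chain_id <- rep(seq_len(chains), each = kept)
  divs <- 0L
  set.seed(seed)
  jitters <- matrix(stats::rnorm(chains * jp$dim, 0, 0.1), chains)
  for (cc in seq_len(chains)) {
    res <- hmc_sample(jp$lp, jp$grad, init + jitters[cc, ],
                      iterations = iterations, warmup = warmup,
                      leapfrog = leapfrog, target_accept = target_accept,
                      seed = seed * 1000 + cc)
    draws[chain_id == cc, ] <- res$draws
    divs <- divs + res$divergences
  }
  # transform non-centered latent draws back to the W scale
  for (i in seq_along(spec$blocks)) {
    b <- spec$blocks[[i]]
    if (b$type == "smooth") {
      e <- eigen(b$penalty, symmetric = TRUE)
      U <- e$vectors; dvals <- pmax(e$values, 0)
      th <- draws[, spec$dim_W + b$theta_idx]
      A <- draws[, b$idx, drop = FALSE] %*% U
      S <- 1 / sqrt(outer(exp(th), dvals) + b$jitter)
      draws[, b$idx] <- (A * S) %*% t(U)
    } else if (b$type == "frailty") {
      th <- draws[, spec$dim_W + b$theta_idx]
      draws[, b$idx] <- draws[, b$idx, drop = FALSE] * exp(-th / 2)
    }
  }
  colnames(draws) <- jp$names
  diag_df <- mcmc_diagnostics(identified_draws(spec, draws), chain_id)
  structure(
    list(draws = draws, chain = chain_id, names = jp$names,
         diagnostics = diag_df, ok = all(diag_df$rhat < 1.01,
                                         na.rm = TRUE),
         divergences = divs, chains = chains,
         iterations = iterations, warmup = warmup, seed = seed,
         dim_W = jp$dim_W),
    class = "mcmc_run")
}

#' @export
print.mcmc_run <- function(x, ...) {
  cat("MCMC oracle run:", x$chains, "chains x", x$iterations,
      "iterations (", x$warmup, "warmup )\n")
  cat("  max rhat:", round(max(x$diagnostics$rhat, na.rm = TRUE), 4),
      " min ESS:", round(min(x$diagnostics$ess, na.rm = TRUE)),
      " divergences:", x$divergences, "\n")
  cat(if (x$ok) "  converged (all rhat < 1.01)\n" else
      "  NOT converged (some rhat >= 1.01)\n")
  invisible(x)
}

# Map raw draws to identified quantities for convergence diagnostics.
# The partial likelihood is invariant to constant shifts of the additive
# predictor, so the constant direction of each spline coefficient block is
# held only by the small diagonal jitter of its prior: it is deliberately
# (near-)unidentified, has enormous marginal variance, and no finite chain
# mixes it.  Convergence is therefore assessed on the identified
# functions: centered smooth values gamma(u) - mean(gamma(u)) on a grid,
# plus every non-smooth coordinate and the hyperparameters, which is what
# all reported summaries are functions of.
identified_draws <- function(spec, draws) {
  out <- list(); nms <- character(0)
  for (b in spec$blocks) {
    if (b$type == "smooth") {
      pts <- stats::quantile(b$u, probs = seq(0.05, 0.95, length.out = 19),
                             names = FALSE)
      Bg <- bspline_eval(b$knots, pts)
      Ball <- bspline_eval(b$knots, b$u)
      G <- draws[, spec$dim_W * 0 + b$idx, drop = FALSE]
      fitted_mean <- G %*% (colMeans(Ball))
      vals <- G %*% t(Bg) - drop(fitted_mean)
      out[[length(out) + 1L]] <- vals
      nms <- c(nms, paste0("gamma_", b$name, "_q", seq_along(pts)))
    } else {
      out[[length(out) + 1L]] <- draws[, b$idx, drop = FALSE]
      nms <- c(nms, spec$coef_names[b$idx])
    }
  }
  if (spec$dim_theta > 0L) {
    out[[length(out) + 1L]] <-
      draws[, spec$dim_W + seq_len(spec$dim_theta), drop = FALSE]
    nms <- c(nms, names(spec$theta_layout))
  }
  m <- do.call(cbind, out)
  colnames(m) <- nms
  m
}

# split-Rhat and a Geyer initial-positive-sequence ESS per parameter
mcmc_diagnostics <- function(draws, chain_id) {
  chains <- unique(chain_id)
  P <- ncol(draws)
  rhat <- numeric(P); ess <- numeric(P)
  for (j in seq_len(P)) {
    # split each chain in half
    halves <- list()
    for (cc in chains) {
      v <- draws[chain_id == cc, j]
      n2 <- floor(length(v) / 2)
      halves <- c(halves, list(v[seq_len(n2)], v[n2 + seq_len(n2)]))
    }
    m <- length(halves); n <- length(halves[[1L]])
    mu <- vapply(halves, mean, numeric(1))
    s2 <- vapply(halves, stats::var, numeric(1))
    Wv <- mean(s2)
    Bv <- n * stats::var(mu)
    vhat <- (n - 1) / n * Wv + Bv / n
    rhat[j] <- if (Wv > 0) sqrt(vhat / Wv) else NA_real_
    # ESS: per-chain autocorrelations, Geyer truncation
    ess_j <- 0
    for (cc in chains) {
      v <- draws[chain_id == cc, j]
      nv <- length(v)
      if (stats::var(v) == 0) next
      ac <- stats::acf(v, lag.max = min(500, nv - 2), plot = FALSE,
                       demean = TRUE)$acf[, 1L, 1L]
      ssum <- 0
      k <- 2L
      while (k + 1L <= length(ac)) {
        pair <- ac[k] + ac[k + 1L]
        if (pair < 0) break
        ssum <- ssum + pair
        k <- k + 2L
      }
      tau <- 1 + 2 * ssum
      ess_j <- ess_j + nv / max(tau, 1)
    }
    ess[j] <- ess_j
  }
  data.frame(parameter = colnames(draws), rhat = rhat, ess = ess,
             stringsAsFactors = FALSE)
}

#' Natural-scale hyperparameter draws from an MCMC run
#'
#' @param run an [run_mcmc()] object.
#' @param spec the model specification (for the transformations).
#' @param coord hyperparameter index (default 1).
#' @return numeric vector of draws of \eqn{\sigma} (or \eqn{\rho}).
#' @export
mcmc_hyper_sd <- function(run, spec, coord = 1) {
  th <- run$draws[, run$dim_W + coord]
  tr <- spec$theta_layout[[coord]]$transform
  if (tr == "minus2log") exp(-th / 2) else exp(th)
}
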