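#' Fit a Cox model by Laplace approximation and adaptive quadrature
#'
#' End-to-end orchestration: builds the risk sets, locates the mode of the
#' Laplace-approximate hyperparameter posterior, lays an adaptive
#' Gauss-Hermite rule over it, solves the inner optimization at every
#' node, forms the Gaussian-mixture approximation
#' \eqn{\tilde\pi(W \mid y) = \sum_k \phi_k\, \tilde\pi_G(W \mid y,
#' \theta_k)}, draws \code{B} independent samples from it, corrects smooth
#' blocks to their sum-to-zero constraint, and summarizes.  Deterministic
#' given \code{seed}.
#'
#' @param spec a [cox_model_spec()].
#' @param k nodes per hyperparameter dimension (default 15).
#' @param B number of posterior draws (default 10000).
#' @param seed RNG seed for the sampling stage.
#' @param level credible level for equal-tailed intervals (default 0.95).
#' @param loglik optional likelihood closure overriding the partial
#'   likelihood (see [quadratic_loglik()]).
#' @param theta_grid_points grid size for the dense renormalized
#'   hyperparameter marginals (default 101; 0 to skip).
#' @param theta_start optional starting value for the hyperparameter mode
#'   search.
#' @return An object of class \code{coxaghq_fit}: mixture
#'   (\code{components}, \code{phi}, \code{rule}), \code{samples} (B x
#'   dim(W), constraint-corrected), \code{summaries} data frame,
#'   \code{theta_grids} dense marginals, \code{log_Z}.
#' @export
fit_cox <- function(spec, k = 15, B = 10000, seed = 1, level = 0.95,
                    loglik = NULL, theta_grid_points = 101,
                    theta_start = NULL) {
  stopifnot(inherits(spec, "cox_model_spec"))
  if (is.null(loglik)) loglik <- pl_closure(spec, build_risk_sets(spec$data))
  dth <- spec$dim_theta

  if (dth == 0L) {
    r <- log_laplace_theta(spec, numeric(0), loglik = loglik)
    rule <- NULL
    comps <- list(list(theta = numeric(0), mean = r$sol$W_hat,
                       chol_precision = r$sol$chol_H))
    phi <- 1
    attr(phi, "log_Z") <- r$log_laplace
    mode <- list(theta_hat = numeric(0), W_hat = r$sol$W_hat)
    theta_grids <- list()
  } else {
    mode <- find_mode_theta(spec, loglik = loglik, start = theta_start)
    rule <- build_rule(mode$theta_hat, mode$curvature, k)
    Kt <- nrow(rule$nodes)
    comps <- vector("list", Kt)
    logv <- numeric(Kt)
    for (kk in seq_len(Kt)) {
      r <- log_laplace_theta(spec, rule$nodes[kk, ], loglik = loglik,
                             start = mode$W_hat)
      logv[kk] <- r$log_laplace
      comps[[kk]] <- list(theta = rule$nodes[kk, ], mean = r$sol$W_hat,
                          chol_precision = r$sol$chol_H)
    }
    phi <- mixture_weights(rule, logv)
    theta_grids <- if (theta_grid_points > 0) {
      theta_marginal_grids(spec, mode, n_grid = theta_grid_points)
    } else list()
  }

  mix <- structure(
    list(components = comps, phi = as.numeric(phi), rule = rule,
         spec = spec, log_Z = attr(phi, "log_Z")),
    class = "cox_mixture_posterior")

  samples <- sample_posterior(mix, B = B, seed = seed)
  samples <- apply_constraints(samples, mix)
  summ <- summarize_samples(samples, mix, level = level)

  structure(
    list(spec = spec, mode = mode, rule = rule, mixture = mix,
         phi = as.numeric(phi), samples = samples, summaries = summ,
         theta_grids = theta_grids, log_Z = attr(phi, "log_Z"),
         B = B, seed = seed, level = level),
    class = "coxaghq_fit")
}

#' @export
print.coxaghq_fit <- function(x, ...) {
  cat("Cox partial-likelihood fit (Laplace + AGHQ)\n")
  cat("  latent dimension:", x$spec$dim_W,
      " hyperparameters:", x$spec$dim_theta, "\n")
  if (!is.null(x$rule)) {
    cat("  quadrature: K =", x$rule$k_per_dim, "per dimension (",
        nrow(x$rule$nodes), "nodes )\n")
    cat("  theta mode:", paste(signif(x$mode$theta_hat, 4), collapse = ", "),
        "\n")
  }
  cat("  posterior draws:", x$B, "\n\n")
  fixed <- grep("^beta_", rownames(x$summaries))
  if (length(fixed)) {
    print(round(x$summaries[fixed, c("mean", "sd", "lower", "upper")], 4))
  }
  for (nm in names(x$theta_grids)) {
    g <- x$theta_grids[[nm]]
    cat(sprintf("  %s: posterior median (natural scale) %.4g\n",
                nm, g$natural_median))
  }
  invisible(x)
}

#' Draw independent samples from the mixture posterior
#'
#' Component indices are multinomial with probabilities \eqn{\phi}; given
#' a component, a draw is \eqn{\hat W_k + R_k^{-1} z} with \eqn{R_k} the
#' retained upper Cholesky factor of the component precision and \eqn{z}
#' standard normal.
#'
#' @param mix a \code{cox_mixture_posterior}.
#' @param B number of draws.
#' @param seed RNG seed.
#' @return object of class \code{posterior_samples}: \code{draws} (B x
#'   dim(W)), \code{component} (index per draw), \code{seed},
#'   \code{constraint_applied}.
#' @export
sample_posterior <- function(mix, B, seed = 1) {
  stopifnot(inherits(mix, "cox_mixture_posterior"), B >= 1)
  d <- length(mix$components[[1L]]$mean)
  K <- length(mix$components)
  set.seed(seed)
  z <- if (K == 1L) rep(1L, B) else {
    sample.int(K, B, replace = TRUE, prob = mix$phi)
  }
  draws <- matrix(0, B, d)
  for (kk in seq_len(K)) {
    rows <- which(z == kk)
    if (!length(rows)) next
    comp <- mix$components[[kk]]
    noise <- matrix(stats::rnorm(d * length(rows)), d, length(rows))
    draws[rows, ] <- t(comp$mean + backsolve(comp$chol_precision, noise))
  }
  colnames(draws) <- mix$spec$coef_names
  structure(list(draws = draws, component = z, seed = seed,
                 constraint_applied = logical(0)),
            class = "posterior_samples")
}

#' Correct samples to a linear constraint (conditioning by kriging)
#'
#' Projects each draw onto the hyperplane \eqn{A x = 0} using its own
#' component's covariance: \eqn{x^* = x - \Sigma_k A^T (A \Sigma_k
#' A^T)^{-1} A x}.  This is exact conditional-Gaussian sampling under the
#' constraint, so the corrected draws are draws from the constrained
#' mixture.  Component means are corrected the same way for mixture-exact
#' summaries.
#'
#' @param samples a [sample_posterior()] object.
#' @param mix the mixture the samples came from.
#' @param A constraint row vector of length dim(W) (zeros outside the
#'   constrained block).
#' @return corrected \code{posterior_samples}.
#' @export
apply_constraint <- function(samples, mix, A) {
  stopifnot(inherits(samples, "posterior_samples"))
  d <- ncol(samples$draws)
  if (length(A) != d) stop("constraint row has wrong length")
  if (all(A == 0)) stop("constraint row is zero")
  K <- length(mix$components)
  for (kk in seq_len(K)) {
    rows <- which(samples$component == kk)
    comp <- mix$components[[kk]]
    R <- comp$chol_precision
    v <- backsolve(R, forwardsolve(t(R), A))   # Sigma_k A^T
    s <- sum(A * v)                            # A Sigma_k A^T
    if (s <= 0) stop("A Sigma A^T is singular for component ", kk)
    if (length(rows)) {
      ax <- drop(samples$draws[rows, , drop = FALSE] %*% A)
      samples$draws[rows, ] <- samples$draws[rows, , drop = FALSE] -
        outer(ax / s, v)
    }
    mix$components[[kk]]$mean <- comp$mean - v * sum(A * comp$mean) / s
  }
  samples$constraint_applied <- c(samples$constraint_applied, TRUE)
  attr(samples, "corrected_mix") <- mix
  samples
}

# apply the sum-to-zero constraint of every smooth block
apply_constraints <- function(samples, mix) {
  for (b in mix$spec$blocks) {
    if (b$type != "smooth") next
    A <- numeric(mix$spec$dim_W)
    A[b$idx] <- b$constraint
    samples <- apply_constraint(samples, mix, A)
    cm <- attr(samples, "corrected_mix")
    if (!is.null(cm)) mix <- cm
  }
  attr(samples, "corrected_mix") <- mix
  samples
}

#' Summarize posterior samples
#'
#' Empirical mean, SD and equal-tailed credible interval per latent
#' coordinate, with mixture-exact means and SDs (law of total
#' expectation/variance over the components) alongside.
#'
#' @param samples a [sample_posterior()] object.
#' @param mix the mixture (constraint-corrected if applicable).
#' @param level credible level (default 0.95).
#' @return data frame with one row per coordinate: \code{mean}, \code{sd},
#'   \code{lower}, \code{upper}, \code{mean_exact}, \code{sd_exact}.
#' @export
summarize_samples <- function(samples, mix, level = 0.95) {
  cm <- attr(samples, "corrected_mix")
  if (!is.null(cm)) mix <- cm
  X <- samples$draws
  alpha <- (1 - level) / 2
  qs <- apply(X, 2L, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  phi <- mix$phi
  means <- vapply(mix$components, function(c) c$mean,
                  numeric(ncol(X)))
  means <- matrix(means, ncol = length(mix$components))
  m_exact <- drop(means %*% phi)
  vdiag <- vapply(mix$components, function(c) {
    diag(chol2inv(c$chol_precision))
  }, numeric(ncol(X)))
  vdiag <- matrix(vdiag, ncol = length(mix$components))
  v_exact <- drop((vdiag + means^2) %*% phi) - m_exact^2
  data.frame(
    mean = colMeans(X), sd = apply(X, 2L, stats::sd),
    lower = qs[1L, ], upper = qs[2L, ],
    mean_exact = m_exact, sd_exact = sqrt(pmax(v_exact, 0)),
    row.names = colnames(X))
}

# Dense renormalized marginals of each hyperparameter: profile of
# log pi_LA along each coordinate through the mode, normalized by
# trapezoid integration.  For a single hyperparameter this is the exact
# (approximate-posterior) marginal up to normalization.
theta_marginal_grids <- function(spec, mode, n_grid = 101, half_width = 5) {
  dth <- length(mode$theta_hat)
  sds <- sqrt(diag(solve(mode$curvature)))
  out <- list()
  for (j in seq_len(dth)) {
    grid <- seq(mode$theta_hat[j] - half_width * sds[j],
                mode$theta_hat[j] + half_width * sds[j],
                length.out = n_grid)
    logv <- vapply(grid, function(t) {
      th <- mode$theta_hat
      th[j] <- t
      mode$value_fn(th)
    }, numeric(1))
    dens <- exp(logv - max(logv))
    Zc <- sum((dens[-1L] + dens[-n_grid]) / 2 * diff(grid))
    dens <- dens / Zc
    tr <- spec$theta_layout[[j]]$transform
    nat <- function(t) if (tr == "minus2log") exp(-t / 2) else exp(t)
    cdf <- c(0, cumsum((dens[-1L] + dens[-n_grid]) / 2 * diff(grid)))
    cdf <- cdf / cdf[n_grid]
    med_theta <- stats::approx(cdf, grid, xout = 0.5, ties = "ordered")$y
    out[[names(spec$theta_layout)[j]]] <- list(
      theta = grid, density = dens, cdf = cdf, transform = tr,
      natural_median = nat(med_theta))
  }
  out
}

#' Sample a hyperparameter from its dense-grid marginal
#'
#' Inverse-CDF sampling (with linear interpolation) from the renormalized
#' dense evaluation of \eqn{\log\tilde\pi_{LA}} along one coordinate,
#' returned on the natural scale (standard deviation, or range).
#'
#' @param fit a [fit_cox()] object.
#' @param coord hyperparameter index or name (default 1).
#' @param B number of draws.
#' @param seed RNG seed.
#' @return numeric vector of natural-scale draws.
#' @export
sample_hyper_sd <- function(fit, coord = 1, B = 10000, seed = 1) {
  g <- if (is.character(coord)) fit$theta_grids[[coord]] else
    fit$theta_grids[[coord]]
  if (is.null(g)) stop("no dense marginal stored for this coordinate")
  set.seed(seed)
  u <- stats::runif(B)
  th <- stats::approx(g$cdf, g$theta, xout = u, ties = "ordered",
                      rule = 2)$y
  if (g$transform == "minus2log") exp(-th / 2) else exp(th)
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' Supremum over the pooled sample points of the absolute difference of
#' the two empirical CDFs; in [0, 1], 0 for identical samples, 1 for
#' disjoint supports.
#'
#' @param a,b numeric samples (non-empty).
#' @return scalar KS statistic.
#' @export
ks_statistic <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty sample")
  pts <- sort(unique(c(a, b)))
  Fa <- findInterval(pts, sort(a)) / length(a)
  Fb <- findInterval(pts, sort(b)) / length(b)
  max(abs(Fa - Fb))
}

#' Posterior predictive draws of the spatial field at new sites
#'
#' For each posterior draw of the observed-site spatial values (and its
#' component's \eqn{\theta}), draws from the conditional Gaussian
#' \eqn{\gamma(s^*) \mid \gamma(s)} under the Matern covariance at that
#' \eqn{\theta}: mean \eqn{\Sigma_{*s}\Sigma_{ss}^{-1}\gamma(s)},
#' covariance \eqn{\Sigma_{**} - \Sigma_{*s}\Sigma_{ss}^{-1}\Sigma_{s*}}.
#' A new site coincident with an observed one reproduces the observed-site
#' value (zero conditional variance).
#'
#' @param fit a [fit_cox()] with a spatial term.
#' @param new_locations L x 2 matrix of prediction coordinates.
#' @param seed RNG seed.
#' @return matrix of draws, B x L.
#' @export
predict_spatial <- function(fit, new_locations, seed = 1) {
  spec <- fit$spec
  bi <- which(vapply(spec$blocks, function(b) b$type == "spatial",
                     logical(1)))
  if (!length(bi)) stop("model has no spatial term")
  b <- spec$blocks[[bi]]
  new_locations <- as.matrix(new_locations)
  B <- nrow(fit$samples$draws)
  L <- nrow(new_locations)
  obs <- b$locations
  # cross and new-site distances
  Dno <- sqrt(outer(new_locations[, 1L], obs[, 1L], "-")^2 +
              outer(new_locations[, 2L], obs[, 2L], "-")^2)
  Dnn <- as.matrix(stats::dist(new_locations))
  set.seed(seed)
  out <- matrix(0, B, L)
  comps <- unique(fit$samples$component)
  for (kk in comps) {
    rows <- which(fit$samples$component == kk)
    th <- fit$mixture$components[[kk]]$theta
    sig <- exp(th[b$theta_idx[1L]])
    rho <- exp(th[b$theta_idx[2L]])
    Css <- matern(b$distances, sig, rho)
    Cns <- matern(Dno, sig, rho)
    Cnn <- matern(Dnn, sig, rho)
    Rss <- chol(Css)
    Wt <- backsolve(Rss, forwardsolve(t(Rss), t(Cns)))  # Css^{-1} Cs n
    condC <- Cnn - Cns %*% Wt
    condC <- (condC + t(condC)) / 2
    ev <- eigen(condC, symmetric = TRUE)
    lam <- pmax(ev$values, 0)
    Croot <- ev$vectors %*% (sqrt(lam) * t(ev$vectors))
    g <- fit$samples$draws[rows, b$idx, drop = FALSE]
    mu <- g %*% Wt                                      # rows x L
    noise <- matrix(stats::rnorm(length(rows) * L), length(rows), L)
    out[rows, ] <- mu + noise %*% Croot
  }
  out
}

#' Exceedance probabilities of the exponentiated field
#'
#' Per location, the fraction of draws whose exponentiated value exceeds
#' the threshold (e.g. relative-risk maps at a threshold of 1.5).
#'
#' @param draws matrix of draws (B x L), on the log scale.
#' @param threshold positive threshold on the exponentiated scale.
#' @return numeric vector of per-location probabilities.
#' @export
exceedance <- function(draws, threshold) {
  draws <- as.matrix(draws)
  if (!nrow(draws)) stop("no draws")
  colMeans(exp(draws) > threshold)
}

#' Evaluate the fitted smooth at covariate values
#'
#' Applies the stored B-spline basis of a smooth term to each posterior
#' draw's coefficient block, giving draws of \eqn{\gamma(u)}.
#'
#' @param fit a [fit_cox()] object.
#' @param term name of the smooth covariate.
#' @param u evaluation points (default: observed covariate values).
#' @return matrix of draws, B x length(u).
#' @export
smooth_values <- function(fit, term, u = NULL) {
  spec <- fit$spec
  bi <- which(vapply(spec$blocks, function(b) {
    b$type == "smooth" && b$name == term
  }, logical(1)))
  if (!length(bi)) stop("no smooth term named ", term)
  b <- spec$blocks[[bi]]
  Bmat <- if (is.null(u)) bspline_eval(b$knots, b$u) else
    bspline_eval(b$knots, u)
  fit$samples$draws[, b$idx, drop = FALSE] %*% t(Bmat)
}
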