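#' Cubic B-spline basis on equally spaced knots
#'
#' Builds the cubic B-spline basis used for semi-parametric smooth terms:
#' \code{n_knots} equally spaced knots spanning the observed covariate
#' range, with boundary knots repeated to full multiplicity, giving
#' \code{d = n_knots + 2} basis functions.  Rows sum to one (partition of
#' unity).
#'
#' @param u numeric covariate vector with at least two distinct values.
#' @param n_knots number of equally spaced knots (>= 4).
#' @return list with \code{basis} (length(u) x d matrix), \code{knots}
#'   (the full knot vector including repeated boundary knots) and
#'   \code{range}.
#' @export
build_bspline_basis <- function(u, n_knots) {
  if (n_knots < 4) stop("n_knots must be at least 4")
  a <- min(u); b <- max(u)
  if (!(b > a)) stop("covariate is constant: cannot build a spline basis")
  inner <- seq(a, b, length.out = n_knots)
  knots <- c(rep(a, 3), inner, rep(b, 3))
  B <- splines::splineDesign(knots, u, ord = 4, outer.ok = TRUE)
  list(basis = B, knots = knots, range = c(a, b))
}

# Evaluate the basis defined by a stored knot vector at new points,
# clamping to the training range (constant extrapolation of basis rows).
bspline_eval <- function(knots, u) {
  a <- knots[4]; b <- knots[length(knots) - 3L]
  u <- pmin(pmax(u, a), b)
  splines::splineDesign(knots, u, ord = 4, outer.ok = TRUE)
}

#' Integrated second-derivative penalty matrix
#'
#' Exact Gram matrix of second derivatives of the cubic B-spline basis,
#' \eqn{S_{ij} = \int \phi_i''(t)\,\phi_j''(t)\,dt}.  Second derivatives of
#' cubic splines are piecewise linear, so their products are piecewise
#' quadratic and a two-point Gauss-Legendre rule on each inter-knot
#' interval integrates them exactly.  The result is symmetric positive
#' semi-definite with a two-dimensional null space spanned by the
#' coefficients of affine functions.
#'
#' @param knots full cubic knot vector as returned by
#'   [build_bspline_basis()].
#' @return d x d penalty matrix.
#' @export
build_penalty <- function(knots) {
  uk <- unique(knots)
  S <- 0
  # 2-point Gauss-Legendre nodes on (-1, 1)
  gl <- c(-1, 1) / sqrt(3)
  for (i in seq_len(length(uk) - 1L)) {
    lo <- uk[i]; hi <- uk[i + 1L]
    h2 <- (hi - lo) / 2
    pts <- (lo + hi) / 2 + h2 * gl
    D2 <- splines::splineDesign(knots, pts, ord = 4, derivs = 2L,
                                outer.ok = TRUE)
    S <- S + h2 * crossprod(D2)      # equal GL weights = 1
  }
  (S + t(S)) / 2
}

#' Matern covariance with shape parameter one
#'
#' \eqn{\nu = 1} Matern covariance,
#' \eqn{C(h) = \sigma^2 (\kappa h) K_1(\kappa h)} with
#' \eqn{\kappa = \sqrt{8\nu}/\rho}, so that \eqn{\rho} is the practical
#' correlation range: the correlation at distance \eqn{h = \rho} is about
#' 0.14.  \eqn{C(0) = \sigma^2}.
#'
#' @param distance nonnegative distances (vector or matrix).
#' @param sigma marginal standard deviation (> 0).
#' @param rho practical correlation range (> 0).
#' @param kappa_factor multiple of \eqn{1/\rho} defining \eqn{\kappa};
#'   default \eqn{\sqrt{8\nu}} with \eqn{\nu = 1}.
#' @return covariance values, same shape as \code{distance}.
#' @export
matern <- function(distance, sigma, rho, kappa_factor = sqrt(8)) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be positive")
  if (!is.numeric(rho) || rho <= 0) stop("rho must be positive")
  if (any(distance < 0)) stop("distances must be nonnegative")
  kh <- (kappa_factor / rho) * distance
  out <- distance
  zero <- kh == 0
  out[zero] <- sigma^2
  khn <- kh[!zero]
  out[!zero] <- sigma^2 * khn * besselK(khn, nu = 1)
  out
}

#' Smooth-term specification
#'
#' @param column name of the covariate column.
#' @param n_knots number of equally spaced knots (default 50).
#' @param prior a [prior_exponential()] on the smoothing standard
#'   deviation \eqn{\sigma} (transform \code{"minus2log"}).
#' @param jitter diagonal jitter added to the spline precision to make it
#'   full rank; default \code{1e-5 * mean(diag(penalty))}.
#' @return a \code{smooth_spec} list.
#' @export
smooth_spec <- function(column, n_knots = 50,
                        prior = prior_exponential(median = 1),
                        jitter = NULL) {
  structure(list(column = column, n_knots = n_knots, prior = prior,
                 jitter = jitter),
            class = "smooth_spec")
}

#' Spatial-term specification
#'
#' Matern (\eqn{\nu = 1}) spatial random effect at the observation
#' coordinates, with hyperparameters \eqn{\theta = (\log\sigma, \log\rho)}.
#'
#' @param prior_sigma exponential prior on the marginal SD
#'   (transform \code{"log"}).
#' @param prior_range exponential prior on the practical range
#'   (transform \code{"log"}).
#' @return a \code{spatial_spec} list.
#' @export
spatial_spec <- function(prior_sigma = prior_exponential(median = 1, transform = "log"),
                         prior_range = prior_exponential(median = 1, transform = "log")) {
  structure(list(prior_sigma = prior_sigma, prior_range = prior_range),
            class = "spatial_spec")
}

#' Build the model specification for an additive Cox predictor
#'
#' Assembles the design structures for the additive predictor
#' \deqn{\eta_{ij} = x_{ij}^T\beta + \sum_q \gamma_q(u_{qij}) + \xi_i
#'   + \gamma_s(s_{ij}),}
#' where \eqn{\beta} are linear effects with independent
#' \eqn{N(0, \code{beta_prior_variance})} priors, each \eqn{\gamma_q} is a
#' penalized cubic B-spline smooth, \eqn{\xi_i} are i.i.d. Gaussian group
#' frailties and \eqn{\gamma_s} is a Matern spatial field.  The latent
#' vector is \eqn{W = (\Gamma_1, \ldots, \Gamma_r, \beta, \xi, \gamma_s)};
#' its prior precision \eqn{Q_\theta} is block diagonal and assembled by
#' [assemble_Q()].  There is no intercept: the partial likelihood is
#' invariant to constant shifts of \eqn{\eta}.
#'
#' @param data a [survival_dataset()].
#' @param linear character vector of covariate columns entering linearly.
#' @param smooths list of [smooth_spec()] terms.
#' @param frailty_prior a [prior_exponential()] on the frailty SD
#'   \eqn{\sigma_\xi} (transform \code{"minus2log"}), or \code{NULL} for no
#'   frailty term.
#' @param spatial a [spatial_spec()], or \code{NULL}.
#' @param beta_prior_variance prior variance of each linear coefficient
#'   (default 1000).
#' @return An object of class \code{cox_model_spec}: design matrix
#'   \code{X} (N x dim(W)), block layout, theta layout with priors.
#' @export
cox_model_spec <- function(data, linear = NULL, smooths = list(),
                           frailty_prior = NULL, spatial = NULL,
                           beta_prior_variance = 1000) {
  stopifnot(inherits(data, "survival_dataset"))
  if (inherits(smooths, "smooth_spec")) smooths <- list(smooths)
  N <- data$total
  blocks <- list()
  theta_layout <- list()
  Xs <- list()
  offset <- 0L

  for (sm in smooths) {
    if (is.null(data$covariates) || !sm$column %in% names(data$covariates)) {
      stop("smooth covariate column not found: ", sm$column)
    }
    u <- data$covariates[[sm$column]]
    bb <- build_bspline_basis(u, sm$n_knots)
    P <- build_penalty(bb$knots)
    d <- ncol(bb$basis)
    jit <- if (is.null(sm$jitter)) 1e-5 * mean(diag(P)) else sm$jitter
    ti <- length(theta_layout) + 1L
    theta_layout[[ti]] <- sm$prior
    names(theta_layout)[ti] <- paste0("theta_smooth_", sm$column)
    blocks[[length(blocks) + 1L]] <- list(
      type = "smooth", name = sm$column, dim = d,
      idx = offset + seq_len(d), penalty = P, jitter = jit,
      knots = bb$knots, u = u, constraint = colSums(bb$basis),
      theta_idx = ti)
    Xs[[length(Xs) + 1L]] <- bb$basis
    offset <- offset + d
  }

  if (!is.null(linear)) {
    if (is.null(data$covariates) || !all(linear %in% names(data$covariates))) {
      stop("linear covariate column(s) not found: ",
           paste(setdiff(linear, names(data$covariates)), collapse = ", "))
    }
    Xl <- as.matrix(data$covariates[linear])
    storage.mode(Xl) <- "double"
    if (any(apply(Xl, 2L, function(col) all(col == col[1L])))) {
      stop("constant (intercept-like) linear column: the partial ",
           "likelihood cannot identify an intercept")
    }
    p <- ncol(Xl)
    blocks[[length(blocks) + 1L]] <- list(
      type = "linear", name = "beta", dim = p, idx = offset + seq_len(p),
      prior_variance = beta_prior_variance, coef_names = colnames(Xl))
    Xs[[length(Xs) + 1L]] <- Xl
    offset <- offset + p
  }

  if (!is.null(frailty_prior)) {
    n <- data$n_groups
    Z <- matrix(0, N, n)
    Z[cbind(seq_len(N), data$group)] <- 1
    ti <- length(theta_layout) + 1L
    theta_layout[[ti]] <- frailty_prior
    names(theta_layout)[ti] <- "theta_frailty"
    blocks[[length(blocks) + 1L]] <- list(
      type = "frailty", name = "xi", dim = n, idx = offset + seq_len(n),
      theta_idx = ti)
    Xs[[length(Xs) + 1L]] <- Z
    offset <- offset + n
  }

  if (!is.null(spatial)) {
    if (is.null(data$coords)) stop("spatial term requires coordinates")
    key <- paste(data$coords[, 1L], data$coords[, 2L], sep = "\r")
    ukey <- unique(key)
    loc_idx <- match(key, ukey)
    uloc <- data$coords[match(ukey, key), , drop = FALSE]
    L <- nrow(uloc)
    D <- as.matrix(stats::dist(uloc))
    Zs <- matrix(0, N, L)
    Zs[cbind(seq_len(N), loc_idx)] <- 1
    ti <- length(theta_layout)
    theta_layout[[ti + 1L]] <- spatial$prior_sigma
    theta_layout[[ti + 2L]] <- spatial$prior_range
    names(theta_layout)[ti + 1:2] <- c("theta_spatial_logsigma",
                                       "theta_spatial_logrange")
    blocks[[length(blocks) + 1L]] <- list(
      type = "spatial", name = "spatial", dim = L, idx = offset + seq_len(L),
      locations = uloc, distances = D, theta_idx = ti + 1:2)
    Xs[[length(Xs) + 1L]] <- Zs
    offset <- offset + L
  }

  if (offset == 0L) stop("model has no terms")
  X <- do.call(cbind, Xs)
  coef_names <- unlist(lapply(blocks, function(b) {
    switch(b$type,
      smooth = paste0("gamma_", b$name, "_", seq_len(b$dim)),
      linear = paste0("beta_", b$coef_names),
      frailty = paste0("xi_", seq_len(b$dim)),
      spatial = paste0("s_", seq_len(b$dim)))
  }))
  colnames(X) <- coef_names
  structure(
    list(data = data, X = X, blocks = blocks, theta_layout = theta_layout,
         dim_W = offset, dim_theta = length(theta_layout),
         coef_names = coef_names),
    class = "cox_model_spec")
}

#' @export
print.cox_model_spec <- function(x, ...) {
  cat("Cox model specification: dim(W) =", x$dim_W,
      ", dim(theta) =", x$dim_theta, "\n")
  for (b in x$blocks) {
    cat("  block", b$type, "(", b$name, "), dim", b$dim, "\n")
  }
  invisible(x)
}

# Per-block prior precision matrices at theta (list, in block order).
Q_block_list <- function(spec, theta) {
  if (length(theta) != spec$dim_theta) stop("theta has wrong length")
  if (any(!is.finite(theta))) stop("non-finite theta")
  lapply(spec$blocks, function(b) {
    switch(b$type,
      smooth = exp(theta[b$theta_idx]) * b$penalty +
        diag(b$jitter, b$dim),
      linear = diag(1 / b$prior_variance, b$dim),
      frailty = diag(exp(theta[b$theta_idx]), b$dim),
      spatial = {
        sig <- exp(theta[b$theta_idx[1L]])
        rho <- exp(theta[b$theta_idx[2L]])
        C <- matern(b$distances, sig, rho)
        R <- tryCatch(chol(C), error = function(e) {
          stop("spatial covariance factorization failed at theta = (",
               paste(signif(theta[b$theta_idx], 4), collapse = ", "), ")")
        })
        chol2inv(R)
      })
  })
}

#' Assemble the prior precision of the latent vector
#'
#' Block-diagonal precision \eqn{Q_\theta} of
#' \eqn{W \mid \theta \sim N(0, Q_\theta^{-1})}: spline blocks
#' \eqn{e^{\theta_q} S_q + \mathrm{jitter} \cdot I} (the small diagonal
#' jitter makes the rank-deficient smoothing penalty full rank without
#' altering its conditional-independence pattern), linear block
#' \eqn{I/\mathrm{prior\ variance}}, frailty block \eqn{e^{\theta_0} I},
#' spatial block the inverse Matern covariance.
#'
#' @param spec a [cox_model_spec()].
#' @param theta numeric vector matching the theta layout.
#' @return dim(W) x dim(W) symmetric positive-definite matrix.
#' @export
assemble_Q <- function(spec, theta) {
  Qb <- Q_block_list(spec, theta)
  Q <- matrix(0, spec$dim_W, spec$dim_W)
  for (i in seq_along(spec$blocks)) {
    idx <- spec$blocks[[i]]$idx
    Q[idx, idx] <- Qb[[i]]
  }
  Q
}

# log|Q_theta| via per-block Cholesky factors.
logdet_Q <- function(spec, theta) {
  Qb <- Q_block_list(spec, theta)
  sum(vapply(Qb, function(M) 2 * sum(log(diag(chol(M)))), numeric(1)))
}

#' Additive predictor from the latent vector
#'
#' \eqn{\eta = X W}: linear in \eqn{W} by construction.
#'
#' @param spec a [cox_model_spec()].
#' @param W latent vector of length \code{spec$dim_W}.
#' @return numeric vector of length N.
#' @export
eta_from_W <- function(spec, W) {
  if (length(W) != spec$dim_W) stop("W has wrong length")
  drop(spec$X %*% W)
}
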