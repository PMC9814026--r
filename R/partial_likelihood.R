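#' Log partial likelihood of a Cox model
#'
#' Breslow-tied log partial likelihood
#' \deqn{\ell(\eta) = \sum_{(i,j): d_{ij}=1} \Big[\eta_{ij} -
#'   \log \sum_{(l,k) \in R_{ij}} e^{\eta_{lk}}\Big],}
#' where the risk set \eqn{R_{ij}} contains every observation (event or
#' censored) with observed time \eqn{\ge y_{ij}}.  Evaluated with one
#' reverse-cumulative log-sum-exp sweep over the time-sorted array
#' (O(N log N) for the sort, O(N) per evaluation), with a running-max
#' shift for numerical stability.  The value is invariant to adding a
#' constant to \eqn{\eta}, which is why the model carries no intercept.
#'
#' @param eta numeric vector of additive predictors, one per observation
#'   (original row order).
#' @param risk a [build_risk_sets()] index.
#' @return scalar log partial likelihood.
#' @export
log_partial_likelihood <- function(eta, risk) {
  stopifnot(inherits(risk, "risk_set_index"))
  if (length(eta) != risk$n) stop("eta has wrong length")
  if (any(!is.finite(eta))) stop("non-finite eta")
  ev <- risk$event_positions
  if (length(ev) == 0L) return(0)
  es <- eta[risk$order]
  m <- max(es)
  suff <- rev(cumsum(rev(exp(es - m))))   # suffix sums of exp(eta - m)
  logS <- m + log(suff)                   # log risk-set sums per start pos
  sum(es[ev] - logS[risk$risk_start[ev]])
}

# Internal: value, gradient, and curvature ingredients of the log partial
# likelihood with respect to eta, in sorted order.  Returns:
#   value, g_sorted (gradient wrt sorted eta),
#   w1 (e^{eta_i} * C_i, the diagonal weight of the first Hessian term),
#   Bn (n_events x N-free structure handled by caller via suffix sums).
pl_eta_core <- function(eta, risk) {
  es <- eta[risk$order]
  N <- risk$n
  m <- max(es)
  ee <- exp(es - m)
  suff <- rev(cumsum(rev(ee)))
  ev <- risk$event_positions
  st <- risk$risk_start[ev]
  S <- suff[st]                       # scaled risk-set sums, one per event
  value <- sum(es[ev]) - length(ev) * m - sum(log(S))
  # C_i = sum over events with risk_start <= i of 1/S_e (scaled consistently)
  b <- numeric(N)
  for (k in seq_along(ev)) b[st[k]] <- b[st[k]] + 1 / S[k]
  C <- cumsum(b)
  w1 <- ee * C                        # in (0, #events]
  g_sorted <- risk$event_sorted - w1
  list(value = value, g_sorted = g_sorted, w1 = w1, ee = ee, S = S, st = st)
}

#' Partial-likelihood value, gradient and Hessian with respect to W
#'
#' Chain rule through the linear map \eqn{\eta = X W}: the gradient is
#' \eqn{X^T \nabla_\eta \ell} and the Hessian is the dense
#' \eqn{\dim(W) \times \dim(W)} matrix
#' \eqn{X^T \nabla^2_\eta \ell\, X}, accumulated per risk set with suffix
#' sums so the N x N Hessian in \eqn{\eta} is never formed.  The Hessian
#' of \eqn{-\ell} is positive semi-definite (log-concavity of the partial
#' likelihood).
#'
#' @param spec a [cox_model_spec()].
#' @param W latent vector.
#' @param risk a [build_risk_sets()] index.
#' @param hessian if \code{FALSE}, skip the Hessian (cheaper; used by the
#'   MCMC oracle).
#' @return list with \code{value}, \code{gradient} (length dim(W)) and
#'   \code{neg_hessian} (dim(W) x dim(W) curvature of \eqn{-\ell}), or
#'   \code{NULL} when \code{hessian = FALSE}.
#' @export
pl_derivatives <- function(spec, W, risk, hessian = TRUE) {
  eta <- eta_from_W(spec, W)
  Xs <- spec$X[risk$order, , drop = FALSE]
  core <- pl_eta_core(eta, risk)
  grad <- unname(drop(crossprod(Xs, core$g_sorted)))
  nh <- NULL
  if (hessian) {
    # term 1: sum_i e^{eta_i} C_i x_i x_i^T
    H1 <- crossprod(Xs, Xs * core$w1)
    # term 2: sum_e a_e a_e^T with a_e = (1/S_e) * suffix-sum of e^{eta} x
    SufX <- apply(Xs * core$ee, 2L, function(col) rev(cumsum(rev(col))))
    SufX <- matrix(SufX, nrow = risk$n)
    A <- SufX[core$st, , drop = FALSE] / core$S
    H2 <- crossprod(A)
    nh <- H1 - H2                      # curvature of -ell, PSD
    nh <- unname((nh + t(nh)) / 2)
    dimnames(nh) <- NULL
  }
  list(value = core$value, gradient = grad, neg_hessian = nh)
}

#' Differenced predictor state
#'
#' The partial likelihood depends on \eqn{\eta} only through differences
#' \eqn{\Delta_{ij} = \eta_{\mathrm{ref}} - \eta_{ij}} relative to a
#' reference observation (whose entry is exactly zero).  By default the
#' reference is the first record in input order.
#'
#' @param eta numeric predictor vector.
#' @param reference_index index of the reference observation (default 1).
#' @return list of class \code{predictor_state} with \code{eta},
#'   \code{delta}, \code{reference_index}.
#' @export
delta_from_eta <- function(eta, reference_index = 1L) {
  if (reference_index < 1L || reference_index > length(eta)) {
    stop("reference_index out of range")
  }
  structure(list(eta = eta, delta = eta[reference_index] - eta,
                 reference_index = as.integer(reference_index)),
            class = "predictor_state")
}

#' Log partial likelihood from a differenced predictor state
#'
#' Equals [log_partial_likelihood()] at the underlying \eqn{\eta}: the
#' likelihood is a function of \eqn{\Delta} alone, and
#' \eqn{\eta = \eta_{\mathrm{ref}} - \Delta} differs from \eqn{-\Delta}
#' by a constant, to which \eqn{\ell} is invariant.
#'
#' @param state a [delta_from_eta()] predictor state.
#' @param risk a [build_risk_sets()] index.
#' @return scalar log partial likelihood.
#' @export
log_partial_likelihood_delta <- function(state, risk) {
  stopifnot(inherits(state, "predictor_state"))
  log_partial_likelihood(-state$delta, risk)
}
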