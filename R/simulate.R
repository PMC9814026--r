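#' Piecewise baseline hazards
#'
#' Baseline hazards for the synthetic-data generators.  Two kinds:
#' \code{piecewise_constant} (rates on intervals between breakpoints, last
#' rate extended to infinity) and \code{piecewise_linear} (hazard values
#' at breakpoints, linear in between, constant after the last breakpoint).
#' The cumulative hazard \eqn{H_0} and its inverse are closed form
#' (piecewise linear, resp. piecewise quadratic), so inverse-transform
#' survival-time sampling is exact.
#'
#' @param breaks increasing breakpoint times starting at 0.
#' @param values for \code{piecewise_constant}: one rate per interval
#'   (length = length(breaks)); for \code{piecewise_linear}: hazard value
#'   at each breakpoint (same length as breaks).
#' @param kind hazard kind.
#' @return object of class \code{baseline_hazard} with functions
#'   \code{h(t)}, \code{H(t)}, \code{Hinv(x)}.
#' @export
baseline_hazard <- function(breaks, values,
                            kind = c("piecewise_constant",
                                     "piecewise_linear")) {
  kind <- match.arg(kind)
  stopifnot(breaks[1L] == 0, !is.unsorted(breaks, strictly = TRUE),
            all(values >= 0))
  nb <- length(breaks)
  if (kind == "piecewise_constant") {
    stopifnot(length(values) == nb)
    if (values[nb] <= 0) stop("last rate must be positive (finite mass)")
    Hb <- c(0, cumsum(values[-nb] * diff(breaks)))
    h <- function(t) values[pmax(findInterval(t, breaks), 1L)]
    H <- function(t) {
      i <- pmax(findInterval(t, breaks), 1L)
      Hb[i] + values[i] * (t - breaks[i])
    }
    Hinv <- function(x) {
      i <- pmax(findInterval(x, Hb), 1L)
      breaks[i] + (x - Hb[i]) / values[i]
    }
  } else {
    stopifnot(length(values) == nb)
    if (values[nb] <= 0) stop("hazard after last breakpoint must be positive")
    # cumulative hazard at breakpoints (trapezoids)
    Hb <- c(0, cumsum((values[-nb] + values[-1L]) / 2 * diff(breaks)))
    slope <- c(diff(values) / diff(breaks), 0)
    h <- function(t) {
      i <- pmax(findInterval(t, breaks), 1L)
      i <- pmin(i, nb)
      pmax(values[i] + slope[i] * (t - breaks[i]), 0)
    }
    H <- function(t) {
      i <- pmin(pmax(findInterval(t, breaks), 1L), nb)
      dt <- t - breaks[i]
      Hb[i] + values[i] * dt + slope[i] * dt^2 / 2
    }
    Hinv <- function(x) {
      i <- pmin(pmax(findInterval(x, Hb), 1L), nb)
      dH <- x - Hb[i]
      a <- slope[i] / 2
      b <- values[i]
      dt <- ifelse(abs(a) < 1e-12, dH / b,
                   (-b + sqrt(pmax(b^2 + 4 * a * dH, 0))) / (2 * a))
      breaks[i] + dt
    }
  }
  structure(list(kind = kind, breaks = breaks, values = values,
                 h = h, H = H, Hinv = Hinv),
            class = "baseline_hazard")
}

#' Stock baseline hazards for the simulation studies
#'
#' Three wiggliness levels: \code{"simple"}, a two-level step
#' (0.05 on [0, 15), 0.15 after); \code{"oscillating"}, a step alternating
#' 0.05/0.25 with period 5; \code{"complicated"}, a continuous hazard that
#' switches between linear ramps (slope +/- 0.04) and constants on
#' length-2 intervals with floor 0.01.  The numeric levels are package
#' defaults chosen to give event times on a scale of tens of time units;
#' all are overridable through [baseline_hazard()].
#'
#' @param name one of \code{"simple"}, \code{"oscillating"},
#'   \code{"complicated"}.
#' @return a [baseline_hazard()].
#' @export
stock_baseline <- function(name = c("simple", "oscillating", "complicated")) {
  name <- match.arg(name)
  switch(name,
    simple = baseline_hazard(c(0, 15), c(0.05, 0.15)),
    oscillating = baseline_hazard(
      seq(0, 30, by = 5), rep(c(0.05, 0.25), length.out = 7),
      kind = "piecewise_constant"),
    complicated = {
      # ramp up / hold / ramp down / hold, period 8, on [0, 40]
      br <- seq(0, 40, by = 2)
      vals <- 0.01 + 0.08 * rep(c(0, 1, 1, 0), length.out = length(br))
      baseline_hazard(br, vals, kind = "piecewise_linear")
    })
}

#' Sample survival times under a Cox hazard
#'
#' Inverse-transform sampling from \eqn{h(t) = h_0(t) e^\eta}:
#' \eqn{T = H_0^{-1}(E e^{-\eta})} with \eqn{E \sim} Exponential(1),
#' exact for the closed-form piecewise cumulative hazards.
#'
#' @param h0 a [baseline_hazard()].
#' @param eta vector of additive predictors.
#' @return vector of survival times, one per element of \code{eta}.
#' @export
sample_survival_times <- function(h0, eta) {
  stopifnot(inherits(h0, "baseline_hazard"))
  E <- stats::rexp(length(eta))
  h0$Hinv(E * exp(-eta))
}

#' Random right-censoring of a fixed fraction
#'
#' Selects a uniformly random subset of \code{round(rate * N)}
#' observations; each selected observation gets a censoring time drawn
#' Uniform(0, t) and indicator 0.  Selecting the subset independently of
#' the times implies independent censoring.
#'
#' @param times vector of event times.
#' @param rate censoring fraction in [0, 1).
#' @return list with \code{y} (observed times) and \code{d} (indicators).
#' @export
apply_random_censoring <- function(times, rate) {
  stopifnot(rate >= 0, rate < 1)
  N <- length(times)
  y <- times
  d <- rep(1L, N)
  nc <- round(rate * N)
  if (nc > 0) {
    sel <- sample.int(N, nc)
    y[sel] <- stats::runif(nc, 0, times[sel])
    d[sel] <- 0L
  }
  list(y = y, d = d)
}

#' Simulation study 1: sparse Gaussian frailties
#'
#' n groups (default 60) of m observations each; frailties
#' \eqn{\xi_i \sim N(0, \sigma_\xi^2)}; one standard-normal covariate with
#' linear effect \eqn{\beta = 0.2}; survival times from the simple step
#' baseline; 10\% random right-censoring.
#'
#' @param m observations per group.
#' @param sigma_xi frailty standard deviation.
#' @param seed RNG seed.
#' @param n_groups number of groups (default 60).
#' @param beta linear effect (default 0.2).
#' @param censor_rate censoring fraction (default 0.1).
#' @param h0 baseline hazard (default \code{stock_baseline("simple")}).
#' @return list with \code{data} (a [survival_dataset()]) and
#'   \code{truth} (true beta, frailties, censor rate, seed).
#' @export
simulate_study1 <- function(m, sigma_xi, seed = 1, n_groups = 60,
                            beta = 0.2, censor_rate = 0.1,
                            h0 = stock_baseline("simple")) {
  stopifnot(m >= 1)
  set.seed(seed)
  N <- n_groups * m
  xi <- stats::rnorm(n_groups, 0, sigma_xi)
  x <- stats::rnorm(N)
  grp <- rep(seq_len(n_groups), each = m)
  eta <- beta * x + xi[grp]
  t_true <- sample_survival_times(h0, eta)
  cz <- apply_random_censoring(t_true, censor_rate)
  data <- survival_dataset(cz$y, cz$d, group = grp,
                           covariates = data.frame(x = x))
  truth <- list(beta = beta, frailties = xi, sigma_xi = sigma_xi,
                censor_rate = censor_rate, seed = seed, eta = eta)
  list(data = data, truth = truth)
}

#' Simulation study 2: sinusoidal nonlinear effect
#'
#' n independent observations (default 1000); covariate
#' \eqn{u \sim} Unif(-6, 6); predictor
#' \eqn{\eta = \gamma(u) = 1.5[\sin(0.8u) + 1]}; baseline from the named
#' family; 10\% random right-censoring.
#'
#' @param baseline baseline name for [stock_baseline()].
#' @param seed RNG seed.
#' @param n number of observations (default 1000).
#' @param censor_rate censoring fraction (default 0.1).
#' @return list with \code{data} and \code{truth} (true \eqn{\gamma(u_i)},
#'   both raw and centered to mean zero over the sample, the scale on
#'   which the sum-to-zero-constrained estimate is comparable).
#' @export
simulate_study2 <- function(baseline = c("simple", "oscillating",
                                         "complicated"),
                            seed = 1, n = 1000, censor_rate = 0.1) {
  h0 <- stock_baseline(match.arg(baseline))
  set.seed(seed)
  u <- stats::runif(n, -6, 6)
  gam <- 1.5 * (sin(0.8 * u) + 1)
  t_true <- sample_survival_times(h0, gam)
  cz <- apply_random_censoring(t_true, censor_rate)
  data <- survival_dataset(cz$y, cz$d,
                           covariates = data.frame(u = u))
  truth <- list(gamma = gam, gamma_centered = gam - mean(gam), u = u,
                censor_rate = censor_rate, seed = seed)
  list(data = data, truth = truth)
}

#' Replication metrics: MSE and interval coverage
#'
#' \code{mse} is the mean squared difference between posterior means and
#' truths; \code{coverage} the fraction of credible intervals containing
#' the truth.
#'
#' @param estimates posterior means.
#' @param truths true values, same length.
#' @param lower,upper interval endpoints (optional).
#' @return list with \code{mse} and (when intervals given)
#'   \code{coverage}.
#' @export
replication_metrics <- function(estimates, truths, lower = NULL,
                                upper = NULL) {
  if (length(estimates) != length(truths)) stop("length mismatch")
  out <- list(mse = mean((estimates - truths)^2))
  if (!is.null(lower)) {
    if (length(lower) != length(truths) || length(upper) != length(truths)) {
      stop("length mismatch")
    }
    out$coverage <- mean(lower <= truths & truths <= upper)
  }
  out
}

#' Write a simulated dataset to CSV (+ truth sidecar)
#'
#' @param sim output of [simulate_study1()] or [simulate_study2()].
#' @param path CSV output path; the truth sidecar goes to
#'   \code{paste0(path, ".truth.json")}.
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(sim, path) {
  d <- sim$data
  df <- data.frame(group = d$group, time = d$time, status = d$event)
  if (!is.null(d$covariates)) df <- cbind(df, d$covariates)
  utils::write.csv(df, path, row.names = FALSE)
  tp <- paste0(path, ".truth.json")
  jsonlite::write_json(sim$truth, tp, auto_unbox = TRUE, digits = NA)
  invisible(c(path, tp))
}
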