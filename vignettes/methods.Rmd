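---
title: "Approximate Bayesian inference for Cox models with partial likelihood"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Approximate Bayesian inference for Cox models with partial likelihood}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`coxaghq` performs Bayesian inference for Cox proportional hazards models
using the *partial* likelihood, so that the baseline hazard $h_0(t)$ is
never modelled or estimated.  Observation $j$ in group $i$ has hazard
$h_{ij}(t) = h_0(t)\,e^{\eta_{ij}}$ with additive predictor

$$\eta_{ij} = x_{ij}^T\beta \;+\; \sum_q \gamma_q(u_{qij}) \;+\; \xi_i
\;+\; \gamma_s(s_{ij}),$$

where $\beta$ are linear effects with $N(0, 1000)$ priors (the
conventional vague prior; the variance is configurable), each
$\gamma_q$ is a smooth function represented by a cubic B-spline basis
with an integrated-second-derivative (O'Sullivan) penalty, the
$\xi_i \sim N(0, \sigma_\xi^2)$ are i.i.d. group frailties capturing
within-group correlation of survival times, and $\gamma_s$ is a
Gaussian field with Matérn covariance (shape $\nu = 1$) over spatial
coordinates.  There is no intercept: the partial likelihood

$$\ell(\eta) = \sum_{(i,j)\,:\,d_{ij}=1}
  \Big[\eta_{ij} - \log\!\!\sum_{(l,k)\in R_{ij}}\!\! e^{\eta_{lk}}\Big],
\qquad R_{ij} = \{(l,k): y_{lk} \ge y_{ij}\},$$

is invariant to constant shifts of $\eta$, which also motivates the
sum-to-zero constraint imposed on each fitted smooth.  Ties are handled
with the Breslow convention throughout: tied events share the full
common risk set, and censored observations at an event time are inside
that event's risk set.  The likelihood is evaluated in $O(N)$ after one
sort, by a reverse-cumulative log-sum-exp sweep; its gradient and dense
Hessian are computed analytically *with respect to the latent vector*
$W = (\Gamma, \beta, \xi, \gamma_s)$ rather than the $N$ linear
predictors, so the dense Hessian has fixed, small dimension regardless
of the sample size.

Variance-type hyperparameters are collected in
$\theta$ on unconstrained scales ($\theta = -2\log\sigma$ for smooth
and frailty standard deviations; $\log\sigma$ and $\log\rho$ for the
Matérn parameters) and given exponential priors on the natural scale,
specified through a median or a tail probability.

## The approximation

For fixed $\theta$, the conditional posterior
$\pi(W \mid \theta, y) \propto \exp\{-\tfrac12 W^TQ_\theta W +
\ell(\eta(W))\}$ is strictly log-concave ($Q_\theta$ positive definite,
$\ell$ concave), so its mode $\hat W_\theta$ is unique and found
reliably by Newton iterations with step-halving (tolerance $10^{-8}$ on
the max-norm gradient, at most 50 iterations).  A second-order
expansion at the mode gives a Gaussian approximation with precision
$H_\theta = Q_\theta - \nabla^2\ell$, and the Tierney–Kadane identity
gives the Laplace approximation to the hyperparameter posterior,

$$\log\tilde\pi_{LA}(\theta \mid y) = \log\pi(\theta)
 + \tfrac12\log|Q_\theta| - \tfrac12\log|H_\theta|
 - \tfrac12\hat W_\theta^TQ_\theta\hat W_\theta + \ell(\hat W_\theta)
 + \text{const}.$$

The spline penalty is rank-deficient (affine functions are free), so a
small jitter — $10^{-5}$ times the mean penalty diagonal, a scale-free
choice that preserves the penalty's conditional-independence pattern —
is added to its diagonal to make $Q_\theta$ full rank.

$\tilde\pi_{LA}$ is maximized over $\theta$ by BFGS with
central-difference gradients (step $10^{-4}$; inner solves are
warm-started, which uniqueness makes safe), followed by Newton
polishing; the curvature at the mode (differenced gradients, step
$10^{-3}$) adapts a Gauss–Hermite product rule: nodes
$\theta_k = \hat\theta + \sqrt2\,L z_k$ with $LL^T$ the inverse
curvature.  The posterior of $W$ is then the Gaussian mixture
$\sum_k \phi_k\,\tilde\pi_G(W \mid y, \theta_k)$ with
$\phi_k \propto \tilde\pi_{LA}(\theta_k\mid y)\,\delta_k$.  With one
node per dimension the rule degenerates to a pure Laplace
approximation; the rule integrates its own adapted Gaussian exactly for
every $K$.  $K$ counts nodes per hyperparameter dimension; the package
defaults to $K = 15$ for frailty models and accepts the smaller values
($7$, $4$) appropriate when $\dim\theta$ grows.

Sampling draws a component index from Multinomial$(\phi)$ and then a
Gaussian draw through the retained Cholesky factor of $H_{\theta_k}$;
$B = 10{,}000$ draws is the default.  Each smooth block is then
corrected to its sum-to-zero constraint by conditioning by kriging,
$x^* = x - \Sigma_kA^T(A\Sigma_kA^T)^{-1}Ax$, using each draw's own
component covariance — exact conditional-Gaussian sampling, verified
against brute-force conditioning in the tests.  Summaries report both
empirical moments of the draws and mixture-exact moments (law of total
expectation/variance); the two are reported side by side because either
could be quoted as "the" posterior mean.

Hyperparameter marginals are not taken from the discrete node set:
a dense renormalized evaluation of $\tilde\pi_{LA}$ along each
coordinate (through the mode, 101 points over $\pm5$ posterior SDs)
gives a smooth marginal from which natural-scale draws are produced by
inverse-CDF interpolation.  For a single hyperparameter this *is* the
Laplace marginal, exactly normalized.

## The MCMC oracle

Validation compares the approximation against a Hamiltonian Monte
Carlo sampler targeting the *exact* joint posterior
$\pi(W, \theta \mid y)$ under the same partial likelihood and priors.
Design choices that matter:

* **Non-centered parameterization.**  Smooth blocks are reparameterized
  through the eigendecomposition of their penalty and frailty blocks by
  $\xi = e^{-\theta/2}V$, removing the funnel geometry that makes
  centered HMC mix slowly in variance parameters.  Draws are mapped
  back to the $W$ scale afterwards; the target is unchanged.
* **Dense metric.**  A shrunk full covariance estimated from mid-warmup
  draws whitens the strong posterior correlations among spline
  coefficients; step size follows dual averaging (target acceptance
  0.8), with jittered leapfrog trajectory lengths.
* **Diagnostics on identified quantities.**  The constant direction of
  a spline block is held only by the prior jitter — it is deliberately
  near-unidentified under the shift-invariant likelihood and no finite
  chain mixes it.  Split-$\hat R$ and effective sample sizes are
  therefore computed on identified functions: centered smooth values on
  a grid, all other latent coordinates, and $\theta$.  A run qualifies
  as an oracle when all $\hat R < 1.01$.

## Synthetic data

The generators reproduce two study designs.  *Sparse frailties*: 60
groups of $m$ observations, $\xi_i \sim N(0, \sigma_\xi^2)$, one
standard-normal covariate with effect $\beta = 0.2$, and 10% of
observations selected uniformly at random for right-censoring with
censoring time drawn Uniform$(0, t)$ — selecting the subset
independently of the times gives independent censoring by construction.
*Nonlinear effect*: 1000 independent observations with
$u \sim \mathrm{Unif}(-6, 6)$ and $\eta = 1.5[\sin(0.8u) + 1]$.
Survival times use exact inverse-transform sampling through closed-form
piecewise cumulative hazards.  Three stock baselines of increasing
wiggliness are provided (two-level step; alternating step; a continuous
ramp/hold pattern); their numeric levels are package defaults chosen to
put event times on a scale of tens of time units, and they are fully
overridable.  Because the partial likelihood depends on the data only
through the ranking of times and the censoring pattern, posterior
comparisons are nearly insensitive to the baseline's exact shape.

What the generators deliberately do not emulate: covariate-dependent or
informative censoring, left truncation, time-varying covariates, and
ties (simulated times are continuous almost surely).  Passing tests on
these data therefore say nothing about those features of real data.

## Problem sizes and tolerances in the test suite

The validation suite runs at sizes chosen to make each comparison
sharp: brute-force likelihood checks at $N \le 60$; the kidney-catheter
analysis at its natural size ($N = 76$) with $K = 15$ and
$B = 10{,}000$; sparse-frailty MCMC comparisons on single replications
at $m = 2$ and $m = 10$; the nonlinear-effect comparison at $n = 200$
with 30 knots and $K = 7$; and interval-coverage properties over 100
(smooth effect, $n = 300$) and 200 (linear effect, $m = 5$)
replications.  Oracle chains in the tests use shorter, well-diagnosed
runs (all split-$\hat R$ checked); the acceptance script uses 4 chains
of 35,000 iterations with 25,000 warmup.  Kolmogorov–Smirnov
comparisons against published single-replication values use bands
(0.04–0.07) sized for the combination of replication-to-replication
variation — the published values come from one simulated dataset whose
seed is unknown — and residual sampler noise; the kidney comparisons,
where the identical dataset is available, reproduce the published
KS statistics closely (0.089 vs 0.083 for $\sigma_\xi$ in a
representative run).

## Numerical choices and edge cases

* Degenerate rules: $K = 1$ is accepted and equals the Laplace
  approximation; models with no hyperparameters (linear effects only)
  skip the quadrature entirely and return a single-component fit.
* Event-free data make $\ell \equiv 0$: the inner mode is exactly 0,
  the determinant terms cancel, and the hyperparameter posterior
  reduces to the prior — kept exact and tested.
* A Gaussian (quadratic) log-likelihood substituted for $\ell$ makes
  every stage exact; the pipeline then reproduces the conjugate
  closed-form posterior and marginal likelihood to $10^{-6}$, which is
  the strongest end-to-end correctness check in the suite.
* The Matérn practical range uses $\kappa = \sqrt{8\nu}/\rho$
  (correlation $\approx 0.14$ at distance $\rho$).  The threshold is a
  convention; `matern()` exposes the $\kappa$ factor for users who
  prefer a different one.
* Spline basis convention: `n_knots` equally spaced knots spanning the
  observed covariate range with boundary knots at full multiplicity,
  giving basis dimension `n_knots + 2`; evaluation outside the observed
  range clamps to the boundary.
* The reference observation for the differenced-predictor view
  ($\Delta_{ij} = \eta_{\mathrm{ref}} - \eta_{ij}$) is the first record
  in input order; all outputs are invariant to this choice (tested).

## Known limitations

The Laplace approximation for $\pi(\sigma_\xi \mid y)$ degrades when
frailties are sparse (few observations per group): the approximate
marginal is visibly shifted relative to MCMC at $m = 2$ even though
latent-field inference remains accurate.  This is an inherent property
of the method, quantified rather than hidden by the KS comparisons.
Efron tie handling, stratified partial likelihoods, left truncation,
interval censoring, competing risks, tensor-product smooths and sparse
(SPDE) spatial approximations are out of scope.  The spatial term
inverts a dense Matérn covariance once per hyperparameter node, which
is intended for at most a few thousand distinct locations.
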