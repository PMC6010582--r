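---
title: "Joint modelling of a longitudinal biomarker and disease onset with SNP effects: models, simulation design and numerical choices"
author: "jmsnp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint modelling methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Prospective cohorts such as glucose/diabetes follow-up studies record a
biomarker repeatedly (fasting plasma glucose at scheduled visits) together
with the time until a clinical event (type-2-diabetes onset). A genetic
variant may raise the biomarker trajectory, raise the event hazard
directly, or both. The statistical difficulty is that the biomarker is an
*endogenous* time-varying covariate: once diabetes is diagnosed the patient
is treated, so post-event glucose values are missing by design and the
missingness depends on the latent trajectory itself. Feeding the raw
measurements into a Cox model (the common practice) both ignores
measurement error and mishandles this event-driven dropout.

`jmsnp` implements the shared-parameter joint model for this setting, the
fast two-step approximation used for genome-wide scans, the extended Cox
comparator, a closed-form simulation engine, and the evaluation harness
that compares the estimators over scenario grids.

# Model

For individual $i$ with genotype dosage $z_i \in [0,2]$ and baseline
covariates $w_i$, the observed biomarker at visit time $t_{ij}$ is

$$Y_{ij} = X_i(t_{ij}) + \varepsilon_{ij}, \qquad
  X_i(t) = \theta_{0i} + \theta_{1i}\,t + \gamma z_i + \delta^\top w_i,
  \qquad \varepsilon_{ij} \sim N(0, \sigma^2),$$

with random intercept and slope
$(\theta_{0i}, \theta_{1i}) \sim N_2(\mu, \Sigma)$. The event hazard is

$$\lambda_i(t) = \lambda_0(t)\,
  \exp\{\beta X_i(t) + \alpha z_i + \eta^\top w_i\},$$

so $\gamma$ is the per-allele effect on the biomarker (mmol/L), $\alpha$
the direct per-allele log-hazard-ratio, and $\beta$ the link between the
error-free trajectory and the hazard (log hazard per mmol/L). The baseline
hazard is piecewise constant with two interior knots. Conditional on
$(\theta_{0i}, \theta_{1i})$ the longitudinal and survival processes are
independent, which gives the joint likelihood

$$L_i = \int p(Y_i \mid b)\,
  \lambda_i(T_i)^{\Delta_i} e^{-\int_0^{T_i}\lambda_i(s)\,ds}\,
  \phi(b; \mu, \Sigma)\, db .$$

Because $X_i$ is affine in $t$ and $\lambda_0$ piecewise constant, the
inner cumulative hazard has a closed form (integrals of
$e^{\beta\theta_{1i}s}$ over the constant-rate pieces); only the 2-D
random-effect integral is numerical.

## Estimators

* **JM** (`fit_joint`) maximizes the integrated likelihood. The
  random-effect integral uses *adaptive* Gauss–Hermite quadrature: for
  every subject the integrand's mode is found by a 2-D Newton search (the
  log integrand is strictly concave, so the search is globally
  convergent), nodes are recentred at the mode and rescaled by the
  curvature, and a 5-point-per-dimension product rule (25 nodes) is
  applied. Quadrature is exact whenever the integrand is Gaussian — in
  particular at $\beta = 0$, where the likelihood factorizes into the
  separate longitudinal and survival likelihoods; this factorization is
  the central correctness oracle in the tests.
* **TS** (`fit_two_step`) fits the linear mixed model by maximum
  likelihood, plugs each subject's empirical-Bayes trajectory
  $X^*_i(t) = \hat\theta_{0i} + \hat\theta_{1i}t + \hat\gamma z_i$ into
  the Cox partial likelihood (evaluated exactly at event times), and
  reports naive plug-in standard errors. It deliberately reproduces the
  approximation whose attenuation of $\beta$ the evaluation module
  quantifies; no uncertainty propagation or bootstrap is offered because
  that would change the method under study.
* **Extended Cox** (`build_locf_episodes` + `fit_cox`) carries the last
  observed biomarker value forward over counting-process episodes
  `(start, stop]` and fits the Breslow partial likelihood. Its bias for
  $\beta$ comes from ignoring the measurement error and the step-function
  approximation of a continuously varying covariate.

## Inference

Standard errors come from the inverse central-difference Hessian of the
integrated log-likelihood at the maximum (delta method for the log-scale
variance components); Wald tests use the normal reference. The joint SNP
effect can also be tested by a likelihood-ratio test comparing the full
joint model to the model with the SNP removed from the survival sub-model
($\alpha = 0$, $\chi^2_1$ reference), via `lrt_snp_effect`.

# Simulation engine

`desir_defaults()` carries the generative truth used throughout: 4,352
individuals, 4 visits evenly spaced over a 9-year horizon, incidence
0.0384, allele frequency 0.244, $\mu = (4.55, 0.0108)$,
$\Sigma = \begin{pmatrix} 0.143 & -0.00109 \\ -0.00109 & 6.8\times10^{-4}
\end{pmatrix}$, $\gamma = 0.0229$, $\alpha = 0.265$, $\beta = 3.17$,
$\sigma = 0.305$. These are the conditions every default, test and
acceptance computation uses.

Event times are drawn by inverse transform: with constant baseline rate
$\lambda$ the cumulative hazard is invertible in closed form,

$$T_i = \frac{1}{\beta\theta_{1i}}
  \log\!\left(1 - \frac{\beta\theta_{1i}\,\log(1-u)}
  {\lambda \exp\{\beta\theta_{0i} + (\beta\gamma + \alpha)z_i\}}\right),
  \qquad u \sim U(0,1).$$

When $\beta\theta_{1i} < 0$ the cumulative hazard is bounded and the log
argument can go non-positive: the event never occurs and the individual is
censored administratively — handled as a regular case, not an error. At
$\beta\theta_{1i} = 0$ the exponential limit applies. Every simulated
cohort satisfies the per-draw identity $H_i(T_i) = -\log(1-u_i)$ to
$10^{-8}$, which the tests assert.

The baseline rate is *calibrated*, not guessed: `calibrate_lambda` solves
$E\,[1 - e^{-H(9)}] = d$ for $\lambda$ by monotone root-finding, with the
expectation over $(\theta, z)$ computed deterministically (40-point
Gauss–Hermite per dimension over the random-effect law, exact sum over the
three dosages with Hardy–Weinberg weights). Deterministic integration was
chosen over Monte Carlo so the calibration itself is reproducible.

Dropout is event-driven: measurements strictly after
$\min(T_i, \text{horizon})$ are removed, the baseline measurement is
always retained, and there is no other loss to follow-up. For $m \neq 4$
the schedule generalizes to $m$ evenly spaced visits on $[0, 9]$ including
both endpoints.

## What the generator does not emulate

Real cohort data add features the generator deliberately omits: visit
times jitter around the schedule, measurement error can be skewed and
state-dependent, covariates (age, sex, BMI) shift both processes, the
trajectory need not be linear, and missingness also arises from plain
attrition. Passing tests therefore demonstrate correctness of the
estimators *under the stated generative model* — recovery of the
generating parameters, calibrated error rates, the documented ranking of
methods — not robustness to real-data violations of it. The fitting code
does accept baseline covariates in both sub-models ($\delta$, $\eta$),
although the simulation study never generates them.

# Numerical choices

* **Knots** at the event-time tertiles (33.3%/66.7% percentiles), the
  equal-probability default; degenerate event-time distributions (fewer
  than 3 events, or coincident tertiles) raise errors rather than
  guessing.
* **Optimization** is direct quasi-Newton (L-BFGS-B) on the integrated
  likelihood, started from the two-step fit; convergence tolerance
  `factr = 1e7` (relative likelihood change about $2\times10^{-9}$).
  An EM strategy was not needed: with the two-step start the quasi-Newton
  path converges in well under 200 evaluations.
* **Parameterization.** $\Sigma$ through its Cholesky factor (estimates
  stay positive semi-definite), $\sigma$ and the baseline rates on the
  log scale. The rates are optimized as
  $\log\{\lambda_k e^{\beta \bar{x}}\}$ with $\bar{x}$ the cohort-mean
  biomarker level: the raw rates are of order $10^{-9}$ (the hazard
  multiplies them by $e^{\beta X}$ with $X \approx 4.5$) and lie on a
  ridge with $\beta$; the centred rates are of the order of the crude
  event rate and nearly orthogonal to $\beta$, which is what makes the
  optimization reliable.
* **Mode search.** The per-subject Newton search runs one full step past
  a $10^{-9}$ step tolerance, leaving an $O(10^{-18})$ error, so the
  likelihood value does not depend on the warm start carried across
  optimizer evaluations. The compiled kernel (`src/joint_ll.cpp`) mirrors
  a pure-R reference implementation and the two are cross-checked in the
  tests; the likelihood itself is verified against dense-grid 2-D
  integration on small cohorts.
* **Ties** use the Breslow approximation everywhere (simulated event
  times are continuous almost surely); risk sets use half-open episodes
  $(start, stop]$.
* **Seeds.** Every stochastic routine takes an explicit seed;
  per-scenario and per-replicate streams are derived by an integer hash
  (`derive_seed`) so methods see identical data within a replicate and
  any slice of a study can be reproduced in isolation.

# Problem sizes used by the shipped checks

The full design (240 scenarios × 500 replicates) is a cluster-scale
computation. The package's own checks run desk-scale versions whose Monte
Carlo error is accounted for in the assertions (three-MC-SE bands):
incidence calibration with 20 cohorts of n = 4,352; mixed-model recovery
of $\gamma$ with 50 cohorts of n = 5,000; oracle Cox recovery of
$(\beta, \alpha)$ with 20 cohorts of n = 10,000; type-I error of the TS
SNP tests with 150 replicates at n = 1,000; and the method comparison on
an n ∈ {250, 500, 1000} slice at d = 0.1 with 50 replicates, where the
reported quantities are the RMSE ordering (JM, TS below extended Cox for
$\beta$) and the monotone decrease of the JM RMSE with n. The spiked-scan
check uses n = 20,000 so that the causal variant's expected trajectory
z-score (≈5) separates it from 19 null variants; at the cohort's own
sample size the same effects give a z-score near 2 and single-variant
detection is not expected.

# Known limitations

* Only a linear time trend and a univariate biomarker; no SNP×time
  interaction (deliberately excluded from the study design).
* Exponential simulation baseline and piecewise-constant fitting baseline
  only; no Weibull/spline baselines, stratification, left truncation,
  competing risks, or Efron ties.
* Two-step standard errors are intentionally naive (see above).
* The evaluation harness reports convergence-failure rates rather than
  retrying failed fits with new starts; a failed replicate is excluded
  from accuracy summaries and counted in the failure rate.
* The closed-form retrospective power of the joint effect
  $\beta\gamma + \alpha$ is not implemented (the reference for its
  formula is external); empirical power from the harness replaces it.
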