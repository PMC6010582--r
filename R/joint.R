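# Shared-parameter joint likelihood estimator.
#
# Likelihood per individual:
#   L_i = int p(Y_i | b_i) * lambda_i(T_i)^Delta_i * exp(-int_0^{T_i}
#         lambda_i(s) ds) * p(b_i) db_i
# with lambda_i(t) = lambda0(t) exp(beta * X_i(t) + alpha * z_i + eta'W_i),
# X_i(t) = b0_i + b1_i t + gamma z_i + delta'W_i, b_i ~ N2(mu, Sigma) and
# lambda0 piecewise constant with two interior knots.  The cumulative
# hazard over each constant-rate piece is available in closed form
# (integral of exp(beta*b1*s)), so the only numerical integration is the
# 2-D random-effect integral, approximated by adaptive Gauss-Hermite
# quadrature: nodes are recentred at each subject's posterior mode of b_i
# and rescaled by the posterior curvature.  The log integrand is strictly
# concave in b_i, so the per-subject Newton mode search is globally
# convergent.

#' Piecewise-constant baseline hazard specification
#'
#' @param knots two interior knot locations (years), `0 < k1 < k2`.
#' @param rates optional three positive piece rates (initial values; the
#'   fit estimates them).
#' @return An object of class `baseline_spec`.
#' @export
baseline_spec <- function(knots, rates = NULL) {
  stopifnot(length(knots) == 2, knots[1] > 0, knots[2] > knots[1])
  if (!is.null(rates)) stopifnot(length(rates) == 3, all(rates > 0))
  structure(list(knots = as.numeric(knots), rates = rates),
            class = "baseline_spec")
}

#' Adaptive Gauss-Hermite quadrature specification
#'
#' @param points quadrature points per dimension (default 5, i.e. 25
#'   nodes in 2-D); must be at least 3.
#' @return An object of class `quadrature_spec` carrying the node grid.
#' @export
quadrature_spec <- function(points = 5L) {
  stopifnot(points >= 3)
  gh <- pracma::gaussHermite(points)
  grid <- expand.grid(x1 = gh$x, x2 = gh$x)
  structure(list(points = as.integer(points),
                 x1 = grid$x1, x2 = grid$x2,
                 logw = log(as.vector(outer(gh$w, gh$w))) +
                   grid$x1^2 + grid$x2^2),
            class = "quadrature_spec")
}

#' Place baseline-hazard knots at event-time tertiles
#'
#' Interior knots at the 33.3% and 66.7% percentiles of the observed
#' event times (equal-probability placement), strictly inside the
#' follow-up window.
#'
#' @param surv data.frame `id`, `time`, `status`.
#' @return Numeric vector of two knot locations.
#' @export
choose_knots <- function(surv) {
  et <- surv$time[surv$status == 1]
  if (length(et) < 3) stop("need at least 3 events to place knots")
  k <- unname(stats::quantile(et, c(1, 2) / 3, type = 7))
  if (k[1] <= 0 || k[2] <= k[1]) {
    stop("degenerate event-time distribution: cannot place two distinct knots")
  }
  k
}

# ---- internal data layout -------------------------------------------------

prep_joint_data <- function(cohort, knots, include_genotype = TRUE,
                            include_covariates = TRUE, dosage = NULL) {
  lp <- prep_lme_data(cohort, include_genotype, include_covariates, dosage)
  ids <- lp$ids
  n <- lp$n
  S <- matrix(0, n, 6, dimnames = list(NULL, c("m", "St", "Stt", "Sy",
                                               "Syt", "Syy")))
  for (g in lp$groups) {
    t_ <- g$times
    S[g$idx, "m"] <- length(t_)
    S[g$idx, "St"] <- sum(t_)
    S[g$idx, "Stt"] <- sum(t_^2)
    S[g$idx, "Sy"] <- rowSums(g$Y)
    S[g$idx, "Syt"] <- drop(g$Y %*% t_)
    S[g$idx, "Syy"] <- rowSums(g$Y^2)
  }
  surv <- cohort$survival[match(ids, cohort$survival$id), , drop = FALSE]
  Tv <- surv$time
  bounds <- c(0, knots, Inf)
  lo <- sapply(1:3, function(k) pmin(Tv, bounds[k]))
  hi <- sapply(1:3, function(k) pmin(Tv, bounds[k + 1]))
  # piece index of T: 1 if T <= k1, 2 if k1 < T <= k2, 3 otherwise
  piece <- ifelse(Tv <= knots[1], 1L, ifelse(Tv <= knots[2], 2L, 3L))
  list(env = new.env(parent = emptyenv()),
       xbar = sum(S[, "Sy"]) / sum(S[, "m"]),
       lme = lp, ids = ids, n = n, stats = S, Tv = Tv,
       delta = surv$status, lo = lo, hi = hi, piece = piece,
       knots = knots, z = lp$z, W = lp$W,
       has_geno = lp$has_geno, n_cov = lp$n_cov)
}

# ---- parameter packing ----------------------------------------------------

# The baseline rates are optimized as log(rho_k) with
# rho_k = lambda_k * exp(beta * xbar), xbar the cohort-mean biomarker
# level: the raw rates are astronomically small (the hazard multiplies
# them by exp(beta * X) with X far from zero) and strongly ridge-
# correlated with beta; the centered rates are O(crude event rate) and
# nearly orthogonal to beta, which conditions the optimization.
joint_par_names <- function(has_geno, cov_names) {
  c("mu0", "mu1",
    if (has_geno) "gamma",
    if (length(cov_names)) paste0("delta_", cov_names),
    "l11", "l21", "l22", "log_sigma",
    "log_rho1", "log_rho2", "log_rho3",
    "beta",
    if (has_geno) "alpha",
    if (length(cov_names)) paste0("eta_", cov_names))
}

joint_par_pack <- function(p, has_geno, cov_names, xbar) {
  L <- t(chol(p$Sigma + diag(1e-12, 2)))
  v <- c(p$mu[1], p$mu[2],
         if (has_geno) p$gamma,
         if (length(cov_names)) p$delta,
         log(L[1, 1]), L[2, 1], log(L[2, 2]), log(p$sigma_e),
         log(p$rates) + p$beta * xbar,
         p$beta,
         if (has_geno) p$alpha,
         if (length(cov_names)) p$eta)
  stats::setNames(v, joint_par_names(has_geno, cov_names))
}

joint_par_unpack <- function(par, has_geno, cov_names, xbar) {
  nm <- joint_par_names(has_geno, cov_names)
  par <- stats::setNames(as.numeric(par), nm)
  ncov <- length(cov_names)
  L <- matrix(c(exp(par["l11"]), par["l21"], 0, exp(par["l22"])), 2, 2)
  beta <- unname(par["beta"])
  list(mu = unname(par[c("mu0", "mu1")]),
       Sigma = L %*% t(L),
       sigma_e = exp(unname(par["log_sigma"])),
       gamma = if (has_geno) unname(par["gamma"]) else NULL,
       delta = if (ncov) unname(par[paste0("delta_", cov_names)]) else numeric(0),
       rates = exp(unname(par[c("log_rho1", "log_rho2", "log_rho3")]) -
                     beta * xbar),
       beta = beta,
       alpha = if (has_geno) unname(par["alpha"]) else NULL,
       eta = if (ncov) unname(par[paste0("eta_", cov_names)]) else numeric(0))
}

# ---- log-likelihood -------------------------------------------------------

# Survival pieces: Q(c) = sum_k rate_k * int_{lo_k}^{hi_k} exp(c*s) ds and
# its s- and s^2-weighted companions (the b1-derivatives divide out the
# beta factors at the call sites).  c may be an n-vector or n x Q matrix.
surv_Q <- function(c_, prep, rates, deriv = 0L) {
  f <- switch(deriv + 1L, int_exp, int_s_exp, int_s2_exp)
  out <- 0
  for (k in 1:3) {
    out <- out + rates[k] * f(c_, prep$lo[, k], prep$hi[, k])
  }
  out
}

# all three weighted integrals in one pass, sharing the exponentials
surv_Q012 <- function(c_, prep, rates) {
  Q0 <- Q1 <- Q2 <- 0
  for (k in 1:3) {
    lo <- prep$lo[, k]
    d <- prep$hi[, k] - lo
    w <- c_ * d
    e <- rates[k] * exp(c_ * lo) * d
    p1 <- phi1_f(w); p2 <- phi2_f(w); p3 <- phi3_f(w)
    Q0 <- Q0 + e * p1
    Q1 <- Q1 + e * (lo * p1 + d * p2)
    Q2 <- Q2 + e * (lo^2 * p1 + 2 * lo * d * p2 + d^2 * p3)
  }
  list(Q0 = Q0, Q1 = Q1, Q2 = Q2)
}

# h_i(b0, b1): complete-data log density (longitudinal + survival + prior)
# b0, b1 are n-vectors or n x Q matrices (stats recycle down columns).
# The piecewise cumulative hazard shares the exponentials at the three
# piece boundaries t_k = min(T_i, knot_k):
#   Q(c) = [r1 (E1 - 1) + r2 (E2 - E1) + r3 (E3 - E2)] / c,  E_k = e^{c t_k},
# with a quadratic series in c near zero (exact at c = 0, so the beta = 0
# factorization holds to machine precision).
joint_h <- function(b0, b1, prep, pl, cache) {
  s2 <- pl$sigma_e^2
  S <- prep$stats
  sse <- cache$S_rr - 2 * (b0 * cache$S_r + b1 * cache$S_rt) +
    b0^2 * S[, "m"] + 2 * b0 * b1 * S[, "St"] + b1^2 * S[, "Stt"]
  loglong <- -S[, "m"] / 2 * log(2 * pi * s2) - sse / (2 * s2)
  c_ <- pl$beta * b1
  r <- pl$rates
  h1 <- prep$hi[, 1]; h2 <- prep$hi[, 2]; h3 <- prep$hi[, 3]
  E1 <- exp(c_ * h1); E2 <- exp(c_ * h2); E3 <- exp(c_ * h3)
  Qv <- (r[1] * (E1 - 1) + r[2] * (E2 - E1) + r[3] * (E3 - E2)) / c_
  small <- abs(c_) <= 1e-6
  if (any(small)) {
    Qs <- cache$A1 + c_ * cache$A2 + c_^2 * cache$A3
    Qv[small] <- Qs[small]
  }
  cum <- exp(pmin(pl$beta * b0 + cache$cbase, 700)) * Qv
  event <- prep$delta * (cache$log_rate_T + pl$beta * (b0 + b1 * prep$Tv) +
                           cache$cbase)
  d0 <- b0 - pl$mu[1]; d1 <- b1 - pl$mu[2]
  P <- cache$P
  prior <- -log(2 * pi) - 0.5 * cache$logdetSigma -
    0.5 * (P[1, 1] * d0^2 + 2 * P[1, 2] * d0 * d1 + P[2, 2] * d1^2)
  loglong + event - cum + prior
}

# per-evaluation cache of quantities that depend on params but not on b
joint_cache <- function(prep, pl) {
  o <- rep(0, prep$n)
  cb <- rep(0, prep$n)
  if (prep$has_geno) {
    o <- o + pl$gamma * prep$z
    cb <- cb + pl$alpha * prep$z
  }
  if (prep$n_cov) {
    o <- o + drop(prep$W %*% pl$delta)
    cb <- cb + drop(prep$W %*% pl$eta)
  }
  cbase <- pl$beta * o + cb
  S <- prep$stats
  ch <- chol(pl$Sigma)
  P <- chol2inv(ch)
  h1 <- prep$hi[, 1]; h2 <- prep$hi[, 2]; h3 <- prep$hi[, 3]
  r <- pl$rates
  list(o = o, cbase = cbase,
       S_r = S[, "Sy"] - o * S[, "m"],
       S_rt = S[, "Syt"] - o * S[, "St"],
       S_rr = S[, "Syy"] - 2 * o * S[, "Sy"] + o^2 * S[, "m"],
       P = P, logdetSigma = 2 * sum(log(diag(ch))),
       log_rate_T = log(pl$rates)[prep$piece],
       # series coefficients of the piecewise integral around c = 0
       A1 = r[1] * h1 + r[2] * (h2 - h1) + r[3] * (h3 - h2),
       A2 = (r[1] * h1^2 + r[2] * (h2^2 - h1^2) + r[3] * (h3^2 - h2^2)) / 2,
       A3 = (r[1] * h1^3 + r[2] * (h2^3 - h1^3) + r[3] * (h3^3 - h2^3)) / 6)
}

# posterior mode and curvature of b_i for every individual (vectorized
# damped Newton; the objective is strictly concave).  Modes are
# warm-started from the previous likelihood evaluation of the same fit
# (prep$env) since successive optimizer proposals are close.
joint_modes <- function(prep, pl, cache, max_iter = 50L, tol = 1e-9) {
  s2 <- pl$sigma_e^2
  S <- prep$stats
  P <- cache$P
  beta <- pl$beta
  env <- prep$env
  if (!is.null(env) && !is.null(env$b0) && length(env$b0) == prep$n) {
    b0 <- env$b0; b1 <- env$b1
  } else {
    # Gaussian (longitudinal-only) posterior mode as the cold start
    A11 <- S[, "m"] / s2 + P[1, 1]
    A12 <- S[, "St"] / s2 + P[1, 2]
    A22 <- S[, "Stt"] / s2 + P[2, 2]
    r1 <- cache$S_r / s2 + P[1, 1] * pl$mu[1] + P[1, 2] * pl$mu[2]
    r2 <- cache$S_rt / s2 + P[1, 2] * pl$mu[1] + P[2, 2] * pl$mu[2]
    det0 <- A11 * A22 - A12^2
    b0 <- (A22 * r1 - A12 * r2) / det0
    b1 <- (A11 * r2 - A12 * r1) / det0
  }
  h <- joint_h(b0, b1, prep, pl, cache)
  if (!all(is.finite(h))) return(NULL)
  H00 <- H01 <- H11 <- NULL
  for (it in seq_len(max_iter)) {
    E0 <- exp(pmin(beta * b0 + cache$cbase, 700))
    Q <- surv_Q012(beta * b1, prep, pl$rates)
    g0 <- (cache$S_r - b0 * S[, "m"] - b1 * S[, "St"]) / s2 +
      prep$delta * beta - beta * E0 * Q$Q0 -
      (P[1, 1] * (b0 - pl$mu[1]) + P[1, 2] * (b1 - pl$mu[2]))
    g1 <- (cache$S_rt - b0 * S[, "St"] - b1 * S[, "Stt"]) / s2 +
      prep$delta * beta * prep$Tv - beta * E0 * Q$Q1 -
      (P[1, 2] * (b0 - pl$mu[1]) + P[2, 2] * (b1 - pl$mu[2]))
    H00 <- -S[, "m"] / s2 - beta^2 * E0 * Q$Q0 - P[1, 1]
    H01 <- -S[, "St"] / s2 - beta^2 * E0 * Q$Q1 - P[1, 2]
    H11 <- -S[, "Stt"] / s2 - beta^2 * E0 * Q$Q2 - P[2, 2]
    det <- H00 * H11 - H01^2
    st0 <- -(H11 * g0 - H01 * g1) / det
    st1 <- -(-H01 * g0 + H00 * g1) / det
    if (!all(is.finite(st0)) || !all(is.finite(st1))) return(NULL)
    if (max(abs(st0), abs(st1)) < tol) {
      # quadratic regime: take the final full step and stop -- the
      # residual error is O(tol^2), so the mode (hence the likelihood)
      # is independent of the starting point to machine precision
      b0 <- b0 + st0
      b1 <- b1 + st1
      break
    }
    # step halving where the objective would decrease
    lam <- rep(1, prep$n)
    h_new <- h
    for (hv in 1:8) {
      h_new <- joint_h(b0 + lam * st0, b1 + lam * st1, prep, pl, cache)
      bad <- !is.finite(h_new) | h_new < h - 1e-10
      if (!any(bad)) break
      lam[bad] <- lam[bad] / 2
    }
    b0 <- b0 + lam * st0
    b1 <- b1 + lam * st1
    h <- h_new
  }
  if (!is.null(env)) { env$b0 <- b0; env$b1 <- b1 }
  # curvature at the mode (from the last computed quantities)
  E0 <- exp(pmin(beta * b0 + cache$cbase, 700))
  Q <- surv_Q012(beta * b1, prep, pl$rates)
  H00 <- -S[, "m"] / s2 - beta^2 * E0 * Q$Q0 - P[1, 1]
  H01 <- -S[, "St"] / s2 - beta^2 * E0 * Q$Q1 - P[1, 2]
  H11 <- -S[, "Stt"] / s2 - beta^2 * E0 * Q$Q2 - P[2, 2]
  list(b0 = b0, b1 = b1, H00 = H00, H01 = H01, H11 = H11)
}

joint_loglik_prep <- function(pl, prep, quad, use_cpp = TRUE) {
  if (!use_cpp) return(joint_loglik_prep_r(pl, prep, quad))
  cache <- tryCatch(joint_cache(prep, pl), error = function(e) NULL)
  if (is.null(cache)) return(-Inf)
  env <- prep$env
  warm <- !is.null(env) && !is.null(env$b0) && length(env$b0) == prep$n
  S <- prep$stats
  res <- joint_ll_cpp(S[, "m"], S[, "St"], S[, "Stt"],
                      cache$S_r, cache$S_rt, cache$S_rr,
                      prep$Tv, as.numeric(prep$delta), prep$hi,
                      cache$log_rate_T, cache$cbase, pl$rates,
                      pl$beta, pl$sigma_e, pl$mu, cache$P,
                      cache$logdetSigma, quad$x1, quad$x2, quad$logw,
                      if (warm) env$b0 else numeric(prep$n),
                      if (warm) env$b1 else numeric(prep$n),
                      warm)
  if (!isTRUE(res$ok) || !is.finite(res$ll)) return(-Inf)
  if (!is.null(env)) { env$b0 <- res$b0; env$b1 <- res$b1 }
  res$ll
}

# vectorized pure-R reference implementation of the same computation;
# retained as the readable form of the algorithm and cross-checked
# against the compiled kernel in the tests
joint_loglik_prep_r <- function(pl, prep, quad) {
  cache <- tryCatch(joint_cache(prep, pl), error = function(e) NULL)
  if (is.null(cache)) return(-Inf)
  md <- joint_modes(prep, pl, cache)
  if (is.null(md)) return(-Inf)
  a <- -md$H00; bq <- -md$H01; cq <- -md$H11
  if (any(a <= 0) || any(cq <= 0)) return(-Inf)
  u11 <- sqrt(a); u12 <- bq / u11
  arg <- cq - u12^2
  if (any(arg <= 0)) return(-Inf)
  u22 <- sqrt(arg)
  log_detB <- -(log(u11) + log(u22))
  s2x1 <- sqrt(2) * quad$x1
  s2x2 <- sqrt(2) * quad$x2
  B0 <- md$b0 + outer(1 / u11, s2x1) - outer(u12 / (u11 * u22), s2x2)
  B1 <- md$b1 + outer(1 / u22, s2x2)
  Hm <- joint_h(B0, B1, prep, pl, cache)
  Hm <- sweep(Hm, 2L, quad$logw, "+")
  ll_i <- log(2) + log_detB + row_logsumexp(Hm)
  sum(ll_i)
}

#' Joint log-likelihood of the shared-parameter model
#'
#' Evaluates the integrated (marginal) log-likelihood by adaptive
#' Gauss-Hermite quadrature.  Deterministic given the quadrature
#' specification.
#'
#' @param params list with fields `mu` (length 2), `Sigma` (2x2),
#'   `sigma_e`, `gamma` (or `NULL`), `delta`, `rates` (3 positive piece
#'   rates), `beta`, `alpha` (or `NULL`), `eta`.
#' @param cohort A [cohort_data()].
#' @param knots two baseline-hazard knot locations.
#' @param quad A [quadrature_spec()].
#' @param dosage optional dosage override.
#' @return Scalar log-likelihood.
#' @export
joint_loglik <- function(params, cohort, knots, quad = quadrature_spec(),
                         dosage = NULL) {
  prep <- prep_joint_data(cohort, knots,
                          include_genotype = !is.null(params$gamma),
                          include_covariates = length(params$delta) > 0,
                          dosage = dosage)
  joint_loglik_prep(params, prep, quad)
}

# ---- fitting --------------------------------------------------------------

joint_init_from_two_step <- function(cohort, prep, dosage) {
  ts <- fit_two_step(cohort, include_genotype = prep$has_geno,
                     include_covariates = prep$n_cov > 0, dosage = dosage,
                     se = FALSE)
  p1 <- ts$lme$params
  beta <- unname(ts$cox$coefficients["beta"])
  alpha <- if (prep$has_geno) unname(ts$cox$coefficients["alpha"])
  eta <- if (prep$n_cov) {
    unname(ts$cox$coefficients[setdiff(names(ts$cox$coefficients),
                                       c("beta", "alpha"))])
  } else numeric(0)
  # crude piecewise rates: events / person-time per piece, deflated by the
  # cohort-average relative risk at the piece midpoint
  eb <- predict_random_effects(ts$lme)
  o <- rep(0, prep$n)
  if (prep$has_geno) o <- o + p1$gamma * prep$z
  if (prep$n_cov) o <- o + drop(prep$W %*% p1$delta)
  rates <- numeric(3)
  bounds <- c(0, prep$knots, max(prep$Tv))
  for (k in 1:3) {
    pt <- pmax(pmin(prep$Tv, bounds[k + 1]) - bounds[k], 0)
    dk <- sum(prep$delta[prep$piece == k])
    mid <- (bounds[k] + bounds[k + 1]) / 2
    xmid <- eb$theta0_hat + o + eb$theta1_hat * mid
    rr <- mean(exp(pmin(beta * xmid +
                          (if (prep$has_geno) alpha * prep$z else 0) +
                          (if (prep$n_cov) drop(prep$W %*% eta) else 0), 50)))
    rates[k] <- max(dk, 0.5) / max(sum(pt), 1e-8) / max(rr, 1e-10)
  }
  list(mu = p1$mu, Sigma = p1$Sigma, sigma_e = p1$sigma_e,
       gamma = p1$gamma, delta = p1$delta,
       rates = pmax(pmin(rates, 1e3), 1e-10),
       beta = beta, alpha = alpha, eta = eta, two_step = ts)
}

#' Fit the joint model by maximum likelihood
#'
#' Direct quasi-Newton maximization of the adaptive-quadrature
#' integrated likelihood, initialized from the two-step fit (with a
#' moment-based fallback).  Variance components are optimized on a
#' Cholesky / log scale so the estimates stay in the valid region.
#'
#' @param cohort A [cohort_data()] with at least one event.
#' @param quad A [quadrature_spec()].
#' @param baseline optional [baseline_spec()]; by default knots are
#'   placed at event-time tertiles ([choose_knots()]).
#' @param init optional initial parameter list (as in [joint_loglik()]).
#' @param include_genotype,include_covariates model structure switches.
#' @param dosage optional dosage override (per-variant scan).
#' @param fixed named numeric vector of parameters held fixed during
#'   optimization, e.g. `c(alpha = 0)` for the reduced model of the SNP
#'   likelihood-ratio test.  Supported names: `beta`, `alpha`, `gamma`.
#' @param se compute standard errors ([standard_errors()]) after fitting.
#' @param control passed to [stats::nlminb()].
#' @return An object of class `joint_fit`: `params` (natural-scale
#'   estimates), `estimates` and `se` (named vectors), `loglik`,
#'   `converged`, `iterations`, `knots`, `quad`, plus internals used by
#'   [standard_errors()] and [lrt_snp_effect()].
#' @export
fit_joint <- function(cohort, quad = quadrature_spec(), baseline = NULL,
                      init = NULL, include_genotype = TRUE,
                      include_covariates = TRUE, dosage = NULL,
                      fixed = NULL, se = FALSE, control = list()) {
  if (sum(cohort$survival$status) == 0) {
    stop("no events: survival parameters unidentifiable")
  }
  knots <- if (is.null(baseline)) {
    choose_knots(cohort$survival)
  } else {
    baseline$knots
  }
  prep <- prep_joint_data(cohort, knots, include_genotype,
                          include_covariates, dosage)
  cov_names <- colnames(prep$W)
  if (is.null(init)) {
    init <- tryCatch(joint_init_from_two_step(cohort, prep, dosage),
                     error = function(e) NULL)
  }
  if (is.null(init)) {
    # moment fallback: population line, pooled variance, crude rates
    st <- lme_start_values(prep$lme)
    crude <- sum(prep$delta) / sum(prep$Tv)
    init <- list(mu = st$mu, Sigma = st$Sigma + diag(c(1e-4, 1e-6)),
                 sigma_e = st$sigma_e, gamma = st$gamma, delta = st$delta,
                 rates = rep(crude * exp(-0), 3), beta = 0,
                 alpha = if (prep$has_geno) 0, eta = rep(0, prep$n_cov))
    init$rates <- rep(max(crude, 1e-8), 3) * exp(-init$beta * mean(st$mu[1]))
  }
  par0 <- joint_par_pack(init, prep$has_geno, cov_names, prep$xbar)
  nm <- names(par0)
  fixed_idx <- integer(0)
  if (!is.null(fixed)) {
    bad <- setdiff(names(fixed), nm)
    if (length(bad)) stop("cannot fix unknown parameter(s): ",
                          paste(bad, collapse = ", "))
    fixed_idx <- match(names(fixed), nm)
    par0[fixed_idx] <- as.numeric(fixed)
  }
  free <- setdiff(seq_along(par0), fixed_idx)
  full_par <- par0
  negll <- function(pfree) {
    full_par[free] <- pfree
    pl <- joint_par_unpack(full_par, prep$has_geno, cov_names, prep$xbar)
    v <- tryCatch(joint_loglik_prep(pl, prep, quad), error = function(e) -Inf)
    if (!is.finite(v)) return(1e10)
    -v
  }
  # forward-difference gradient with the base value cached from the
  # optimizer's own last objective call: p + 1 likelihood evaluations per
  # gradient instead of 2p for central differences
  last <- new.env(parent = emptyenv())
  negll_c <- function(pfree) {
    v <- negll(pfree)
    last$par <- pfree
    last$val <- v
    v
  }
  grfn <- function(pfree) {
    f0 <- if (!is.null(last$par) && isTRUE(all(last$par == pfree))) {
      last$val
    } else {
      negll(pfree)
    }
    g <- numeric(length(pfree))
    for (j in seq_along(pfree)) {
      h <- 1e-7 * max(abs(pfree[j]), 1)
      pj <- pfree
      pj[j] <- pj[j] + h
      g[j] <- (negll(pj) - f0) / h
    }
    g
  }
  lower <- rep(-Inf, length(free)); upper <- rep(Inf, length(free))
  scale_names <- c("l11", "l22", "log_sigma",
                   "log_rho1", "log_rho2", "log_rho3")
  lower[nm[free] %in% scale_names] <- -25
  upper[nm[free] %in% scale_names] <- 10
  parscale <- rep(1, length(free))
  parscale[nm[free] %in% c("mu1", "l21", "l22")] <- 0.05
  ctl <- utils::modifyList(list(maxit = 500, factr = 1e7,
                                parscale = parscale), control)
  opt <- stats::optim(par0[free], negll_c, gr = grfn, method = "L-BFGS-B",
                      lower = lower, upper = upper, control = ctl)
  full_par[free] <- opt$par
  pl <- joint_par_unpack(full_par, prep$has_geno, cov_names, prep$xbar)
  loglik <- -opt$value
  converged <- is.finite(loglik) && opt$convergence == 0
  opt$iterations <- unname(opt$counts[1])
  opt$message <- opt$message %||% ""
  est <- c(mu0 = pl$mu[1], mu1 = pl$mu[2],
           if (prep$has_geno) c(gamma = pl$gamma),
           if (prep$n_cov) stats::setNames(pl$delta, paste0("delta_", cov_names)),
           sigma_e = pl$sigma_e,
           Sigma00 = pl$Sigma[1, 1], Sigma01 = pl$Sigma[1, 2],
           Sigma11 = pl$Sigma[2, 2],
           lambda1 = pl$rates[1], lambda2 = pl$rates[2],
           lambda3 = pl$rates[3],
           beta = pl$beta,
           if (prep$has_geno) c(alpha = pl$alpha),
           if (prep$n_cov) stats::setNames(pl$eta, paste0("eta_", cov_names)))
  fit <- structure(
    list(params = pl, estimates = est,
         se = stats::setNames(rep(NA_real_, length(est)), names(est)),
         loglik = loglik, converged = converged,
         iterations = opt$iterations, message = opt$message,
         knots = knots, quad = quad, fixed = fixed,
         par = full_par, free = free, prep = prep,
         cov_names = cov_names, n = prep$n,
         n_events = sum(prep$delta)),
    class = "joint_fit")
  if (se) fit <- standard_errors(fit)
  fit
}

#' @export
print.joint_fit <- function(x, ...) {
  cat(sprintf("<joint_fit> n=%d, events=%d, logLik=%.3f, converged=%s (%d iter)\n",
              x$n, x$n_events, x$loglik, x$converged, x$iterations))
  keep <- intersect(c("mu0", "mu1", "gamma", "sigma_e", "beta", "alpha"),
                    names(x$estimates))
  print(round(data.frame(estimate = x$estimates[keep], se = x$se[keep]), 5))
  cat(sprintf("  baseline knots: %.3g, %.3g; rates: %s\n", x$knots[1],
              x$knots[2],
              paste(signif(x$params$rates, 4), collapse = ", ")))
  invisible(x)
}

#' Standard errors from the numerical observed information
#'
#' Central-difference Hessian of the integrated log-likelihood at the
#' maximum, inverted to give the asymptotic covariance of the free
#' parameters; log/Cholesky-scale components are mapped back to the
#' natural scale by the delta method.  A non-positive-definite Hessian
#' is flagged (`se_ok = FALSE`) and leaves `NA` standard errors.
#'
#' @param fit A converged [fit_joint()] result.
#' @return The fit, with `se`, `vcov_free` and `se_ok` filled in.
#' @export
standard_errors <- function(fit) {
  stopifnot(inherits(fit, "joint_fit"))
  prep <- fit$prep; quad <- fit$quad
  cov_names <- fit$cov_names
  full_par <- fit$par; free <- fit$free
  negll <- function(pfree) {
    full_par[free] <- pfree
    pl <- joint_par_unpack(full_par, prep$has_geno, cov_names, prep$xbar)
    v <- tryCatch(joint_loglik_prep(pl, prep, quad), error = function(e) -Inf)
    if (!is.finite(v)) return(1e10)
    -v
  }
  H <- tryCatch(pracma::hessian(negll, fit$par[free]), error = function(e) NULL)
  fit$se_ok <- FALSE
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && all(is.finite(diag(V))) && all(diag(V) > 0)) {
      nm_free <- names(fit$par)[free]
      se_free <- stats::setNames(sqrt(diag(V)), nm_free)
      fit$vcov_free <- V
      fit$se_ok <- TRUE
      direct <- c(mu0 = "mu0", mu1 = "mu1", gamma = "gamma", beta = "beta",
                  alpha = "alpha")
      for (k in names(direct)) {
        if (k %in% names(fit$se) && direct[k] %in% nm_free) {
          fit$se[k] <- se_free[direct[k]]
        }
      }
      if (prep$n_cov) {
        for (cn in cov_names) {
          for (pref in c("delta_", "eta_")) {
            key <- paste0(pref, cn)
            if (key %in% nm_free) fit$se[key] <- se_free[key]
          }
        }
      }
      # delta method for log-scale parameters
      if ("log_sigma" %in% nm_free) {
        fit$se["sigma_e"] <- fit$params$sigma_e * se_free["log_sigma"]
      }
      # lambda_k = exp(log_rho_k - beta * xbar)
      for (k in 1:3) {
        key <- paste0("log_rho", k)
        if (key %in% nm_free) {
          v_log <- V[match(key, nm_free), match(key, nm_free)]
          if ("beta" %in% nm_free) {
            ib <- match("beta", nm_free)
            v_log <- v_log + prep$xbar^2 * V[ib, ib] -
              2 * prep$xbar * V[match(key, nm_free), ib]
          }
          fit$se[paste0("lambda", k)] <-
            fit$params$rates[k] * sqrt(max(v_log, 0))
        }
      }
    }
  }
  if (!fit$se_ok) {
    warning("observed information not positive definite; SEs unavailable")
  }
  fit
}

#' Likelihood-ratio test of the direct SNP effect on the hazard
#'
#' Compares the full joint model with the reduced model in which the
#' SNP is removed from the survival sub-model (`alpha = 0`; the SNP
#' effect on the trajectory is retained).  The statistic is
#' `2 * (loglik_full - loglik_reduced)`, referred to chi-square with 1
#' degree of freedom.  If the reduced likelihood exceeds the full one
#' beyond tolerance the full model is refitted from the reduced
#' solution.
#'
#' @param cohort A [cohort_data()] with genotypes.
#' @param quad A [quadrature_spec()].
#' @param dosage optional dosage override.
#' @param full optional already-fitted full model (saves one fit).
#' @param ... passed to [fit_joint()].
#' @return list `statistic`, `df`, `p`, `full`, `reduced`.
#' @export
lrt_snp_effect <- function(cohort, quad = quadrature_spec(), dosage = NULL,
                           full = NULL, ...) {
  if (is.null(full)) {
    full <- fit_joint(cohort, quad = quad, dosage = dosage, ...)
  }
  red_init <- full$params
  red_init$alpha <- 0
  reduced <- fit_joint(cohort, quad = quad, dosage = dosage,
                       baseline = baseline_spec(full$knots),
                       init = red_init, fixed = c(alpha = 0), ...)
  if (reduced$loglik > full$loglik + 1e-6) {
    refit_init <- reduced$params
    refit <- fit_joint(cohort, quad = quad, dosage = dosage,
                       baseline = baseline_spec(full$knots),
                       init = refit_init, ...)
    if (refit$loglik > full$loglik) full <- refit
  }
  stat <- max(2 * (full$loglik - reduced$loglik), 0)
  list(statistic = stat, df = 1L,
       p = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
       full = full, reduced = reduced)
}
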