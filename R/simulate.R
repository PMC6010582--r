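# Closed-form simulation engine for the shared-parameter generative model:
# a linear random-intercept/random-slope biomarker trajectory with an
# additive SNP effect, an exponential(-baseline) proportional-hazards event
# process driven by the same trajectory, event-driven dropout of the
# biomarker, and administrative censoring at a fixed horizon.

#' Generative parameter set
#'
#' Container for the full simulation truth of the joint model: the
#' biomarker at time `t` for individual `i` carrying `z` effect alleles is
#' `Y = theta0_i + theta1_i * t + gamma * z + e`, with `(theta0, theta1)`
#' bivariate normal `(mu, Sigma)` and `e ~ N(0, sigma_e^2)`, and the event
#' hazard is `lambda0 * exp(beta * X_i(t) + alpha * z)` where `X_i(t)` is
#' the error-free trajectory.
#'
#' @param mu length-2 mean of the random intercept and slope.
#' @param Sigma 2x2 covariance of the random effects (symmetric PSD).
#' @param sigma_e measurement-error standard deviation (> 0).
#' @param gamma per-allele SNP effect on the biomarker.
#' @param alpha per-allele SNP log-hazard effect.
#' @param beta trajectory-hazard link coefficient.
#' @param lambda0 constant baseline hazard rate per year (`NA` until
#'   calibrated with [calibrate_lambda()]).
#' @param f effect-allele frequency in `[0, 1]`.
#' @param horizon administrative censoring time in years (default 9).
#' @param m number of scheduled measurements (>= 2).
#' @param n default cohort size.
#' @param d target incidence proportion over the horizon.
#' @return An object of class `generative_params`.
#' @export
generative_params <- function(mu, Sigma, sigma_e, gamma, alpha, beta,
                              lambda0 = NA_real_, f, horizon = 9,
                              m = 4L, n = NA_integer_, d = NA_real_) {
  stopifnot(length(mu) == 2, is_psd2(Sigma), sigma_e > 0,
            f >= 0, f <= 1, m >= 2, horizon > 0,
            is.na(lambda0) || lambda0 > 0)
  structure(list(mu = as.numeric(mu), Sigma = Sigma,
                 sigma_e = sigma_e, gamma = gamma, alpha = alpha,
                 beta = beta, lambda0 = lambda0, f = f,
                 horizon = horizon, m = as.integer(m),
                 n = as.integer(n), d = d),
            class = "generative_params")
}

#' @export
print.generative_params <- function(x, ...) {
  cat(sprintf(paste0(
    "<generative_params> mu=(%.4g, %.4g), sigma_e=%.4g, gamma=%.4g,\n",
    "  alpha=%.4g, beta=%.4g, lambda0=%s, f=%.4g, horizon=%g, m=%d\n"),
    x$mu[1], x$mu[2], x$sigma_e, x$gamma, x$alpha, x$beta,
    ifelse(is.na(x$lambda0), "<uncalibrated>", sprintf("%.4g", x$lambda0)),
    x$f, x$horizon, x$m))
  invisible(x)
}

#' Reference parameter set of the glucose / type-2-diabetes study
#'
#' The generative values estimated for rs17747324 (*TCF7L2*) in the
#' D.E.S.I.R. cohort, which define the default simulation conditions:
#' n = 4,352 individuals, m = 4 visits over 9 years, incidence d = 0.0384,
#' allele frequency f = 0.244, random effects with mean (4.55, 0.0108)
#' mmol/L and covariance [[0.143, -0.00109], [-0.00109, 6.8e-4]],
#' gamma = 0.0229 mmol/L per allele, alpha = 0.265, beta = 3.17 and
#' measurement-error sd 0.305 mmol/L.  The baseline rate is left
#' uncalibrated; see [calibrate_lambda()].
#'
#' @return A [generative_params()] object.
#' @export
desir_defaults <- function() {
  generative_params(
    mu = c(4.55, 0.0108),
    Sigma = matrix(c(0.143, -0.00109, -0.00109, 6.8e-4), 2, 2),
    sigma_e = 0.305,
    gamma = 0.0229,
    alpha = 0.265,
    beta = 3.17,
    f = 0.244,
    horizon = 9,
    m = 4L,
    n = 4352L,
    d = 0.0384)
}

#' Simulate Hardy-Weinberg genotype dosages
#'
#' @param n number of individuals.
#' @param f effect-allele frequency.
#' @param seed optional integer seed.
#' @return Integer dosage vector, i.i.d. Binomial(2, f).
#' @export
simulate_genotypes <- function(n, f, seed = NULL) {
  stopifnot(f >= 0, f <= 1, n >= 0)
  if (!is.null(seed)) set.seed(seed)
  stats::rbinom(n, 2L, f)
}

#' Simulate bivariate-normal random effects
#'
#' @param n number of individuals.
#' @param mu length-2 mean vector.
#' @param Sigma 2x2 PSD covariance matrix.
#' @param seed optional integer seed.
#' @return n x 2 matrix with columns `theta0`, `theta1`.
#' @export
simulate_random_effects <- function(n, mu, Sigma, seed = NULL) {
  if (!is_psd2(Sigma)) stop("Sigma must be a symmetric PSD 2x2 matrix")
  if (!is.null(seed)) set.seed(seed)
  th <- rmvnorm_psd(n, mu, Sigma)
  colnames(th) <- c("theta0", "theta1")
  th
}

# hazard multiplier A_i = lambda0 * exp(beta*theta0 + (beta*gamma+alpha)*z)
hazard_scale <- function(theta0, z, params) {
  params$lambda0 *
    exp(params$beta * theta0 + (params$beta * params$gamma + params$alpha) * z)
}

#' Cumulative hazard of the generative model
#'
#' `H(t) = lambda0 * exp(beta*theta0 + (beta*gamma + alpha)*z) *
#' int_0^t exp(beta*theta1*s) ds`, vectorized over individuals.
#'
#' @param t evaluation time(s) in years.
#' @param theta0,theta1 random intercept(s) and slope(s).
#' @param z dosage(s).
#' @param params [generative_params()] with a calibrated `lambda0`.
#' @return Cumulative hazard value(s).
#' @export
cumulative_hazard <- function(t, theta0, theta1, z, params) {
  stopifnot(!is.na(params$lambda0))
  hazard_scale(theta0, z, params) * int_exp(params$beta * theta1, 0, t)
}

#' Invert the cumulative hazard to draw an event time
#'
#' Closed-form inverse-transform sampler for the exponential-baseline
#' proportional-hazards model with a linear latent trajectory: solves
#' `H(T) = -log(1 - u)`.  When `beta * theta1 < 0` the cumulative hazard
#' is bounded, so large `u` yield `+Inf` (the event never occurs and the
#' individual is censored administratively).  When `beta * theta1 = 0`
#' the event time is plain exponential.
#'
#' @param theta0,theta1 random intercept(s) and slope(s).
#' @param z dosage(s).
#' @param params [generative_params()] with calibrated `lambda0`.
#' @param u uniform draw(s) in `(0, 1)`.
#' @return Event time(s) in years, possibly `Inf`.
#' @export
event_time_inverse <- function(theta0, theta1, z, params, u) {
  if (any(u <= 0 | u >= 1)) stop("u must lie strictly in (0, 1)")
  stopifnot(!is.na(params$lambda0))
  k <- max(length(theta0), length(theta1), length(z), length(u))
  theta0 <- rep_len(theta0, k); theta1 <- rep_len(theta1, k)
  z <- rep_len(z, k); u <- rep_len(u, k)
  A <- hazard_scale(theta0, z, params)
  cc <- params$beta * theta1
  target <- -log1p(-u)                     # = -log(1-u) > 0
  out <- numeric(k)
  lin <- abs(cc) < 1e-12
  out[lin] <- target[lin] / A[lin]
  arg <- 1 + cc * target / A
  out[!lin & arg <= 0] <- Inf          # bounded cumulative hazard: no event
  pos <- !lin & arg > 0
  out[pos] <- log(arg[pos]) / cc[pos]
  out
}

#' Calibrate the baseline hazard rate to a target incidence
#'
#' Finds `lambda0 > 0` such that the model-implied probability of an
#' event before the administrative horizon equals `target_d`.  The event
#' probability `E[1 - exp(-H(horizon))]` is computed by deterministic
#' numerical integration: Gauss-Hermite quadrature over the bivariate
#' random-effect law and an exact sum over the three dosage values with
#' Hardy-Weinberg weights; the rate is then solved by monotone
#' root-finding on the log scale.
#'
#' @param params [generative_params()]; its `lambda0` field is ignored.
#' @param target_d target incidence proportion in `(0, 1)`; defaults to
#'   `params$d`.
#' @param gh_points Gauss-Hermite points per dimension (default 40).
#' @param tol tolerance on the achieved incidence (default 1e-6).
#' @return The calibrated rate (per year).
#' @export
calibrate_lambda <- function(params, target_d = params$d, gh_points = 40,
                             tol = 1e-6) {
  stopifnot(is.finite(target_d), target_d > 0, target_d < 1)
  gh <- pracma::gaussHermite(gh_points)
  # nodes for N(mu, Sigma): mu + sqrt(2) * L %*% x, weights w/pi (2-D)
  eg <- eigen(params$Sigma, symmetric = TRUE)
  L <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), 2)
  nodes <- as.matrix(expand.grid(x1 = gh$x, x2 = gh$x))
  th <- sweep(sqrt(2) * nodes %*% t(L), 2L, params$mu, "+")
  w_th <- as.vector(outer(gh$w, gh$w)) / pi
  z_vals <- 0:2
  w_z <- stats::dbinom(z_vals, 2, params$f)
  # event probability factorizes as 1 - exp(-lambda * g(theta, z))
  g_th <- exp(params$beta * th[, 1]) *
    int_exp(params$beta * th[, 2], 0, params$horizon)
  g_z <- exp((params$beta * params$gamma + params$alpha) * z_vals)
  gmat <- outer(g_th, g_z)                 # nodes x dosage
  wmat <- outer(w_th, w_z)
  pev <- function(log_lambda) {
    sum(wmat * (1 - exp(-exp(log_lambda) * gmat)))
  }
  lo <- -25; hi <- 10
  if (pev(hi) < target_d) {
    stop(sprintf("target incidence %.4g unattainable; maximum achievable ~%.4g",
                 target_d, pev(hi)))
  }
  r <- stats::uniroot(function(ll) pev(ll) - target_d, c(lo, hi),
                      tol = 1e-12)
  lam <- exp(r$root)
  if (abs(pev(log(lam)) - target_d) > max(tol, 1e-4)) {
    stop("baseline-rate calibration did not reach the requested tolerance")
  }
  lam
}

#' One cell of the simulation grid
#'
#' @param m number of measurements; `n` cohort size; `f` allele
#'   frequency; `d` target incidence; `n_replicates` replicates for the
#'   evaluation harness; `base_seed` seed from which per-replicate
#'   streams are derived.
#' @param n,f,d,n_replicates,base_seed see above.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(m, n, f, d, n_replicates = 50L,
                          base_seed = 20180614L) {
  stopifnot(m >= 2, n >= 1, f >= 0, f <= 1, d > 0, d < 1, n_replicates >= 1)
  structure(list(m = as.integer(m), n = as.integer(n), f = f, d = d,
                 n_replicates = as.integer(n_replicates),
                 base_seed = as.integer(base_seed)),
            class = "scenario_spec")
}

#' Cartesian scenario grid
#'
#' Default grids follow the sensitivity study: `m` in {2,3,4,5}, `n` in
#' {500, 1000, 2500, 5000, 10000}, `f` in {0.05, 0.1, 0.25, 0.5} and `d`
#' in {0.025, 0.05, 0.1} - 240 scenarios.  Ordering is deterministic
#' (fastest-varying first argument) and each scenario receives its own
#' derived base seed.
#'
#' @param m,n,f,d grid vectors (overridable).
#' @param n_replicates replicates per scenario.
#' @param base_seed master seed.
#' @return List of [scenario_spec()] objects.
#' @export
scenario_grid <- function(m = c(2L, 3L, 4L, 5L),
                          n = c(500L, 1000L, 2500L, 5000L, 10000L),
                          f = c(0.05, 0.1, 0.25, 0.5),
                          d = c(0.025, 0.05, 0.1),
                          n_replicates = 50L, base_seed = 20180614L) {
  if (!length(m) || !length(n) || !length(f) || !length(d)) {
    stop("empty scenario grid")
  }
  g <- expand.grid(m = m, n = n, f = f, d = d, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(g)), function(i) {
    scenario_spec(g$m[i], g$n[i], g$f[i], g$d[i], n_replicates,
                  base_seed = derive_seed(base_seed, i))
  })
}

#' Simulate one cohort under the generative model
#'
#' Draws genotypes, random effects and latent event times, builds the
#' visit schedule (`m` evenly spaced visits on `[0, horizon]`, endpoints
#' included), generates noisy measurements, removes every measurement
#' strictly after the observed time `min(T, horizon)` (event-driven
#' dropout), and assembles the validated cohort together with the full
#' simulation truth.
#'
#' @param spec optional [scenario_spec()]; its `m`, `n`, `f`, `d`
#'   override the corresponding `params` fields.
#' @param params [generative_params()].  If `lambda0` is `NA` it is
#'   calibrated on the fly to the target incidence.
#' @param seed integer seed; the same `(spec, params, seed)` always
#'   yields a bit-identical cohort.
#' @return An object of class `simulated_cohort`: list with `cohort`
#'   (a [cohort_data()] whose genotype matrix holds the single simulated
#'   variant `snp1`), `truth` (data.frame `id`, `theta0`, `theta1`, `u`,
#'   `true_time`, `z`), `params` (with the calibrated rate) and
#'   `schedule`.
#' @export
simulate_cohort <- function(spec = NULL, params = desir_defaults(),
                            seed = 1L) {
  if (!is.null(spec)) {
    stopifnot(inherits(spec, "scenario_spec"))
    params$m <- spec$m
    params$f <- spec$f
    if (!is.na(spec$d) && !identical(spec$d, params$d)) {
      params$d <- spec$d
      params$lambda0 <- NA_real_   # force re-calibration at the new target
    }
    n <- spec$n
  } else {
    n <- params$n
  }
  stopifnot(is.finite(n), n >= 1)
  if (is.na(params$lambda0)) {
    params$lambda0 <- calibrate_lambda(params)
  }
  m <- params$m
  schedule <- seq(0, params$horizon, length.out = m)

  set.seed(seed)
  z <- simulate_genotypes(n, params$f)
  th <- simulate_random_effects(n, params$mu, params$Sigma)
  u <- stats::runif(n)
  eps <- matrix(stats::rnorm(n * m, 0, params$sigma_e), n, m)

  true_time <- event_time_inverse(th[, 1], th[, 2], z, params, u)
  t_obs <- pmin(true_time, params$horizon)
  delta <- as.numeric(true_time <= params$horizon)

  ids <- sprintf("id%06d", seq_len(n))
  keep <- outer(rep(1, n), schedule) <= t_obs + 1e-12   # n x m logical
  ymat <- th[, 1] + outer(th[, 2], schedule) + params$gamma * z + eps
  idx <- which(keep, arr.ind = TRUE)
  long <- data.frame(id = ids[idx[, 1]],
                     time = schedule[idx[, 2]],
                     value = ymat[idx],
                     stringsAsFactors = FALSE)
  long <- long[order(idx[, 1], idx[, 2]), , drop = FALSE]
  surv <- data.frame(id = ids, time = t_obs, status = delta,
                     stringsAsFactors = FALSE)
  gm <- genotype_matrix(matrix(as.numeric(z), nrow = 1,
                               dimnames = list("snp1", ids)),
                        effect_allele = "A")
  cohort <- cohort_data(long, surv, genotypes = gm)
  structure(list(cohort = cohort,
                 truth = data.frame(id = ids, theta0 = th[, 1],
                                    theta1 = th[, 2], u = u,
                                    true_time = true_time, z = z,
                                    stringsAsFactors = FALSE),
                 params = params, schedule = schedule),
            class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("<simulated_cohort> n=%d, events=%d (%.2f%%), m=%d visits\n",
              nrow(x$truth), sum(x$cohort$survival$status),
              100 * mean(x$cohort$survival$status), length(x$schedule)))
  invisible(x)
}

#' Write a simulated cohort (tables plus simulation truth) as TSV
#'
#' @param sim A [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return Invisibly, the vector of files written.
#' @export
write_simulated_cohort <- function(sim, dir, prefix = "cohort") {
  stopifnot(inherits(sim, "simulated_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, "_",
                                 c("longitudinal.tsv", "survival.tsv",
                                   "dosages.tsv", "truth.tsv")))
  write_cohort(sim$cohort, paths[1], paths[2])
  write_genotypes(sim$cohort$genotypes, paths[3])
  utils::write.table(sim$truth, paths[4], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(paths)
}
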