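# Independent oracles and small fixtures used across the test files.
# Every oracle is written from first principles (enumeration, dense
# numerical integration, brute-force optimization) and never calls the
# implementation path it checks.

# ---- tiny hand-built cohort ----------------------------------------------

tiny_cohort <- function() {
  long <- data.frame(
    id = c(rep("a", 3), rep("b", 2), rep("c", 3)),
    time = c(0, 3, 6, 0, 3, 0, 3, 6),
    value = c(4.2, 4.5, 4.4, 5.0, 5.4, 4.8, 4.6, 4.7))
  surv <- data.frame(id = c("a", "b", "c"), time = c(7.2, 4.5, 9),
                     status = c(1, 1, 0))
  gm <- genotype_matrix(matrix(c(0, 1, 2), 1,
                               dimnames = list("s1", c("a", "b", "c"))))
  cohort_data(long, surv, genotypes = gm)
}

# a small simulated cohort reused by several test files (built once)
local_sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(n = 600, seed = 424, d = 0.1) {
  key <- paste(n, seed, d)
  if (is.null(local_sim_cache[[key]])) {
    p <- desir_defaults()
    p$d <- d
    p$lambda0 <- NA_real_
    local_sim_cache[[key]] <-
      simulate_cohort(scenario_spec(4, n, 0.244, d), p, seed = seed)
  }
  local_sim_cache[[key]]
}

# ---- Hardy-Weinberg enumeration oracle -----------------------------------

# direct enumeration with exact log-multinomial probabilities (no
# recurrence): P(h | allele counts) over all feasible heterozygote counts
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  rare <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)
  if (rare == 0) return(1)
  hs <- seq(rare %% 2, rare, by = 2)
  lp <- vapply(hs, function(h) {
    nrr <- (rare - h) / 2
    ncc <- n - h - nrr
    lgamma(n + 1) - lgamma(nrr + 1) - lgamma(h + 1) - lgamma(ncc + 1) +
      h * log(2) - (lgamma(2 * n + 1) - lgamma(rare + 1) -
                      lgamma(2 * n - rare + 1))
  }, numeric(1))
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_Aa, hs)]
  sum(pr[pr <= p_obs * (1 + 1e-12)])
}

# ---- Breslow partial-likelihood brute force ------------------------------

# explicit partial log-likelihood for time-varying covariate paths given
# as functions of time; individuals at risk at t iff t <= t_obs
brute_cox_loglik <- function(theta, surv, covfun_list) {
  ev <- which(surv$status == 1)
  ll <- 0
  for (i in ev) {
    e <- surv$time[i]
    risk <- which(surv$time >= e - 1e-12)
    etas <- vapply(risk, function(j) {
      sum(theta * covfun_list[[j]](e))
    }, numeric(1))
    ll <- ll + sum(theta * covfun_list[[i]](e)) - log(sum(exp(etas)))
  }
  ll
}

# ---- closed-form multivariate normal density (for the LME oracle) --------

mvn_logdens <- function(y, mean, V) {
  k <- length(y)
  ch <- chol(V)
  r <- backsolve(ch, y - mean, transpose = TRUE)
  -0.5 * k * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(r^2)
}

# marginal LME log-likelihood assembled independently of lme_loglik()
brute_lme_loglik <- function(mu, Sigma, sigma_e, gamma, cohort) {
  z <- cohort$genotypes$dosage[1, ]
  ids <- cohort$survival$id
  ll <- 0
  for (id in ids) {
    rows <- cohort$longitudinal$id == id
    t_ <- cohort$longitudinal$time[rows]
    y_ <- cohort$longitudinal$value[rows]
    Zt <- cbind(1, t_)
    V <- Zt %*% Sigma %*% t(Zt) + diag(sigma_e^2, length(t_))
    mn <- mu[1] + mu[2] * t_ + gamma * z[[id]]
    ll <- ll + mvn_logdens(y_, mn, V)
  }
  ll
}

# ---- dense-grid integration oracle for the joint likelihood --------------

joint_grid_loglik <- function(pl, cohort, knots, npts = 601, width = 6) {
  z <- cohort$genotypes$dosage[1, ]
  surv <- cohort$survival
  ll <- 0
  for (i in seq_len(nrow(surv))) {
    id <- surv$id[i]
    rows <- cohort$longitudinal$id == id
    t_ <- cohort$longitudinal$time[rows]
    y_ <- cohort$longitudinal$value[rows]
    Tob <- surv$time[i]; del <- surv$status[i]; zi <- z[[id]]
    g0 <- seq(pl$mu[1] - width * sqrt(pl$Sigma[1, 1]),
              pl$mu[1] + width * sqrt(pl$Sigma[1, 1]), length.out = npts)
    g1 <- seq(pl$mu[2] - width * sqrt(pl$Sigma[2, 2]),
              pl$mu[2] + width * sqrt(pl$Sigma[2, 2]), length.out = npts)
    P <- solve(pl$Sigma)
    f <- outer(g0, g1, function(b0, b1) {
      lng <- 0
      for (j in seq_along(t_)) {
        lng <- lng + dnorm(y_[j], b0 + b1 * t_[j] + pl$gamma * zi,
                           pl$sigma_e, log = TRUE)
      }
      bounds <- c(0, knots, Inf)
      cum <- 0
      for (k in 1:3) {
        lo <- pmin(Tob, bounds[k]); hi <- pmin(Tob, bounds[k + 1])
        cc <- pl$beta * b1
        cum <- cum + pl$rates[k] *
          ifelse(abs(cc) < 1e-12, hi - lo, (exp(cc * hi) - exp(cc * lo)) / cc)
      }
      cum <- cum * exp(pl$beta * b0 + (pl$beta * pl$gamma + pl$alpha) * zi)
      pc <- ifelse(Tob <= knots[1], 1, ifelse(Tob <= knots[2], 2, 3))
      evt <- del * (log(pl$rates[pc]) +
                      pl$beta * (b0 + b1 * Tob + pl$gamma * zi) +
                      pl$alpha * zi)
      pri <- -log(2 * pi) - 0.5 * log(det(pl$Sigma)) -
        0.5 * (P[1, 1] * (b0 - pl$mu[1])^2 +
                 2 * P[1, 2] * (b0 - pl$mu[1]) * (b1 - pl$mu[2]) +
                 P[2, 2] * (b1 - pl$mu[2])^2)
      lng + evt - cum + pri
    })
    mx <- max(f)
    ll <- ll + log(sum(exp(f - mx))) + mx +
      log(g0[2] - g0[1]) + log(g1[2] - g1[1])
  }
  ll
}

# piecewise-exponential survival log-likelihood with a static genotype
# effect (no random effects); used for the beta = 0 factorization checks
piecewise_surv_loglik <- function(rates, alpha, surv, z, knots) {
  bounds <- c(0, knots, Inf)
  ll <- 0
  for (i in seq_len(nrow(surv))) {
    Tob <- surv$time[i]; del <- surv$status[i]; zi <- z[i]
    cum <- 0
    for (k in 1:3) {
      cum <- cum + rates[k] *
        max(min(Tob, bounds[k + 1]) - bounds[k], 0)
    }
    cum <- cum * exp(alpha * zi)
    pc <- ifelse(Tob <= knots[1], 1, ifelse(Tob <= knots[2], 2, 3))
    ll <- ll + del * (log(rates[pc]) + alpha * zi) - cum
  }
  ll
}
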