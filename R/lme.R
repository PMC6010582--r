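# Linear mixed-effects estimation for the longitudinal sub-model:
# random intercept and slope, fixed genotype (and covariate) effects,
# maximum likelihood via the closed-form Gaussian marginal likelihood.
#
# Individuals sharing a measurement-time pattern share the same marginal
# covariance matrix, so the likelihood is evaluated per pattern group with
# dense matrix operations; with scheduled visits and event-driven dropout
# there are only as many groups as visit counts, which keeps a full ML fit
# on tens of thousands of individuals fast.

#' Longitudinal sub-model parameters
#'
#' @param mu length-2 fixed means of the random intercept and slope.
#' @param Sigma 2x2 random-effect covariance (symmetric PSD).
#' @param sigma_e residual standard deviation (> 0).
#' @param gamma per-allele genotype effect (or `NULL` when absent).
#' @param delta named vector of covariate effects (may be length 0).
#' @return An object of class `longitudinal_params`.
#' @export
longitudinal_params <- function(mu, Sigma, sigma_e, gamma = NULL,
                                delta = numeric(0)) {
  stopifnot(length(mu) == 2, is_psd2(Sigma), sigma_e > 0)
  structure(list(mu = as.numeric(mu), Sigma = Sigma, sigma_e = sigma_e,
                 gamma = gamma, delta = delta),
            class = "longitudinal_params")
}

# ---- internal data layout -------------------------------------------------

# Per-individual sufficient statistics and per-pattern grouping.
# dosage overrides the cohort's genotype matrix (used by the scan).
prep_lme_data <- function(cohort, include_genotype = TRUE,
                          include_covariates = TRUE, dosage = NULL) {
  ids <- cohort$survival$id
  z <- NULL
  if (include_genotype) {
    z <- if (!is.null(dosage)) {
      as.numeric(dosage)
    } else if (!is.null(cohort$genotypes)) {
      variant_dosage(cohort, 1L)
    }
    if (!is.null(z) && length(z) != length(ids)) {
      stop("dosage vector length does not match the cohort")
    }
  }
  W <- if (include_covariates) covariate_matrix(cohort) else
    matrix(0, length(ids), 0)

  drop <- if (!is.null(z)) is.na(z) else rep(FALSE, length(ids))
  if (any(drop)) {
    ids <- ids[!drop]
    z <- z[!drop]
    W <- W[!drop, , drop = FALSE]
  }

  long <- cohort$longitudinal[cohort$longitudinal$id %in% ids, , drop = FALSE]
  sp_t <- split(long$time, long$id)[ids]
  sp_y <- split(long$value, long$id)[ids]
  key <- vapply(sp_t, function(t) paste(round(t, 9), collapse = ","),
                character(1))
  groups <- lapply(split(seq_along(ids), key), function(ii) {
    tg <- sp_t[[ii[1]]]
    list(idx = ii,
         times = tg,
         Y = do.call(rbind, sp_y[ii]),
         z = if (!is.null(z)) z[ii],
         W = W[ii, , drop = FALSE])
  })
  list(ids = ids, z = z, W = W, groups = groups,
       n = length(ids), n_obs = nrow(long),
       has_geno = !is.null(z), n_cov = ncol(W))
}

# offset per individual in a group: gamma*z + W %*% delta
group_offset <- function(g, gamma, delta) {
  o <- rep(0, length(g$idx))
  if (!is.null(g$z) && !is.null(gamma)) o <- o + gamma * g$z
  if (length(delta)) o <- o + drop(g$W %*% delta)
  o
}

lme_loglik_prep <- function(params, prep) {
  mu <- params$mu; Sg <- params$Sigma; s2 <- params$sigma_e^2
  ll <- 0
  for (g in prep$groups) {
    t_ <- g$times; mg <- length(t_)
    Zt <- cbind(1, t_)
    V <- Zt %*% Sg %*% t(Zt) + diag(s2, mg)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    logdet <- 2 * sum(log(diag(ch)))
    Vinv <- chol2inv(ch)
    o <- group_offset(g, params$gamma, params$delta)
    R <- g$Y - rep(mu[1] + mu[2] * t_, each = nrow(g$Y)) - o
    Q <- rowSums((R %*% Vinv) * R)
    ll <- ll - 0.5 * (nrow(g$Y) * (mg * log(2 * pi) + logdet) + sum(Q))
  }
  ll
}

#' Exact marginal log-likelihood of the longitudinal sub-model
#'
#' The random effects are integrated out in closed form: each
#' individual's measurement vector is multivariate normal with mean
#' `mu0 + mu1*t + gamma*z + W delta` and covariance
#' `Z Sigma Z' + sigma_e^2 I` where `Z = [1, t]`.
#'
#' @param params A [longitudinal_params()] object.
#' @param cohort A [cohort_data()].
#' @param include_genotype,include_covariates whether the genotype /
#'   covariate fixed effects enter the mean.
#' @param dosage optional dosage vector overriding the cohort genotypes.
#' @return Scalar log-likelihood.
#' @export
lme_loglik <- function(params, cohort, include_genotype = !is.null(params$gamma),
                       include_covariates = length(params$delta) > 0,
                       dosage = NULL) {
  prep <- prep_lme_data(cohort, include_genotype, include_covariates, dosage)
  lme_loglik_prep(params, prep)
}

# transformed parameter vector <-> longitudinal_params
lme_par_pack <- function(params) {
  L <- t(chol(params$Sigma + diag(1e-12, 2)))
  c(mu0 = params$mu[1], mu1 = params$mu[2],
    if (!is.null(params$gamma)) c(gamma = params$gamma),
    if (length(params$delta)) params$delta,
    l11 = log(L[1, 1]), l21 = L[2, 1], l22 = log(L[2, 2]),
    log_sigma = log(params$sigma_e))
}

lme_par_unpack <- function(par, has_geno, cov_names) {
  i <- 2L
  gamma <- NULL
  if (has_geno) { gamma <- unname(par[i + 1L]); i <- i + 1L }
  ncov <- length(cov_names)
  delta <- numeric(0)
  if (ncov) {
    delta <- stats::setNames(unname(par[i + seq_len(ncov)]), cov_names)
    i <- i + ncov
  }
  L <- matrix(c(exp(par[i + 1L]), par[i + 2L], 0, exp(par[i + 3L])), 2, 2)
  longitudinal_params(mu = unname(par[1:2]), Sigma = L %*% t(L),
                      sigma_e = exp(unname(par[i + 4L])),
                      gamma = gamma, delta = delta)
}

lme_start_values <- function(prep) {
  y <- unlist(lapply(prep$groups, function(g) as.vector(t(g$Y))))
  t_ <- unlist(lapply(prep$groups, function(g) rep(g$times, nrow(g$Y))))
  id_of <- unlist(lapply(prep$groups, function(g) rep(g$idx, each = length(g$times))))
  X <- cbind(1, t_)
  if (prep$has_geno) X <- cbind(X, prep$z[id_of])
  if (prep$n_cov) X <- cbind(X, prep$W[id_of, , drop = FALSE])
  b <- tryCatch(stats::lm.fit(X, y)$coefficients, error = function(e) NULL)
  if (is.null(b) || anyNA(b)) {
    stop("singular design in the longitudinal sub-model")
  }
  res <- y - X %*% b
  m_bar <- prep$n_obs / prep$n
  v_tot <- stats::var(res)[1]
  ind_mean <- tapply(res, id_of, mean)
  v_b <- max(stats::var(ind_mean) - v_tot / (2 * m_bar), v_tot / 10)
  s_e <- sqrt(max(v_tot - v_b, v_tot / 5))
  sd1 <- sqrt(v_b) / max(unlist(lapply(prep$groups, function(g) max(g$times))), 1)
  cov_names <- colnames(prep$W)
  p0 <- longitudinal_params(
    mu = c(b[1], b[2]),
    Sigma = matrix(c(v_b, 0, 0, sd1^2), 2, 2),
    sigma_e = s_e,
    gamma = if (prep$has_geno) unname(b[3]),
    delta = if (prep$n_cov) {
      stats::setNames(unname(b[2 + as.integer(prep$has_geno) + seq_len(prep$n_cov)]),
                      cov_names)
    } else numeric(0))
  p0
}

#' Fit the linear mixed-effects longitudinal sub-model by ML
#'
#' Maximum-likelihood (not REML) fit of the random-intercept-and-slope
#' model with an additive genotype fixed effect and optional baseline
#' covariates, by quasi-Newton optimization of the closed-form marginal
#' likelihood.  The random-effect covariance is parameterized through
#' its Cholesky factor so the estimate stays positive semi-definite.
#' The fit uses the observed, dropout-truncated records exactly as they
#' stand, which is the naive behaviour whose bias the joint model is
#' designed to remove.
#'
#' @param cohort A [cohort_data()].
#' @param include_genotype include the per-allele dosage fixed effect.
#' @param include_covariates include the baseline covariates, if present.
#' @param dosage optional dosage vector overriding the cohort genotypes
#'   (used by the per-variant scan); individuals with missing dosage are
#'   dropped from the fit.
#' @param se compute standard errors of the fixed effects from the
#'   numerical observed information (default `TRUE`).
#' @param start optional [longitudinal_params()] starting values.
#' @param control list passed to [stats::nlminb()] control.
#' @return An object of class `lme_fit` with elements `params`
#'   ([longitudinal_params()] estimates), `fixef`, `se`, `loglik`,
#'   `converged`, `iterations`, `grad_norm`, `n`, `n_obs`.
#' @export
fit_lme <- function(cohort, include_genotype = TRUE,
                    include_covariates = TRUE, dosage = NULL, se = TRUE,
                    start = NULL, control = list()) {
  prep <- prep_lme_data(cohort, include_genotype, include_covariates, dosage)
  if (prep$n < 2L) stop("need at least two individuals")
  if (prep$has_geno && stats::var(prep$z) == 0) {
    stop("no variation in genotype dosage")
  }
  p0 <- if (is.null(start)) lme_start_values(prep) else start
  par0 <- lme_par_pack(p0)
  cov_names <- colnames(prep$W)
  negll <- function(par) {
    p <- lme_par_unpack(par, prep$has_geno, cov_names)
    -lme_loglik_prep(p, prep)
  }
  ctl <- utils::modifyList(list(rel.tol = 1e-12, iter.max = 500,
                                eval.max = 1000), control)
  opt <- stats::nlminb(par0, negll, control = ctl)
  params <- lme_par_unpack(opt$par, prep$has_geno, cov_names)
  gr <- tryCatch(pracma::grad(negll, opt$par), error = function(e) rep(NA_real_, length(opt$par)))
  grad_norm <- sqrt(sum(gr^2))
  converged <- opt$convergence == 0 ||
    grepl("relative convergence|X-convergence|both X|singular convergence",
          opt$message %||% "")
  fx_names <- c("mu0", "mu1",
                if (prep$has_geno) "gamma",
                cov_names)
  fixef <- stats::setNames(
    c(params$mu, if (prep$has_geno) params$gamma, params$delta), fx_names)
  ses <- stats::setNames(rep(NA_real_, length(fixef)), fx_names)
  vc <- NULL
  if (se) {
    H <- tryCatch(pracma::hessian(negll, opt$par), error = function(e) NULL)
    if (!is.null(H)) {
      vc <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(vc)) {
        dd <- diag(vc)[seq_along(fixef)]
        ses <- stats::setNames(sqrt(pmax(dd, 0)), fx_names)
      }
    }
  }
  structure(list(params = params, fixef = fixef, se = ses,
                 loglik = -opt$objective, converged = converged,
                 iterations = opt$iterations, grad_norm = grad_norm,
                 n = prep$n, n_obs = prep$n_obs, vcov = vc,
                 prep = prep),
            class = "lme_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.lme_fit <- function(x, ...) {
  cat(sprintf("<lme_fit> n=%d (%d obs), logLik=%.3f, converged=%s\n",
              x$n, x$n_obs, x$loglik, x$converged))
  tab <- data.frame(estimate = x$fixef, se = x$se)
  print(round(tab, 5))
  cat(sprintf("  sigma_e=%.4f  Sigma=[%.4g, %.4g; %.4g, %.4g]\n",
              x$params$sigma_e, x$params$Sigma[1, 1], x$params$Sigma[1, 2],
              x$params$Sigma[2, 1], x$params$Sigma[2, 2]))
  invisible(x)
}

#' Empirical-Bayes prediction of subject-level random effects
#'
#' Posterior means (and covariances) of each individual's random
#' intercept and slope given its observed records and the fitted
#' population parameters.  With abundant, precise data the prediction
#' approaches the individual's own least-squares line; with scarce data
#' it shrinks toward the population line.
#'
#' @param fit An [fit_lme()] result (or any object with `params` and
#'   `prep`).
#' @param ids optional subset of individual ids.
#' @return data.frame `id`, `theta0_hat`, `theta1_hat`, with the 2x2
#'   posterior covariances in `attr(, "post_cov")` (array `2 x 2 x n`).
#' @export
predict_random_effects <- function(fit, ids = NULL) {
  params <- fit$params; prep <- fit$prep
  mu <- params$mu; s2 <- params$sigma_e^2
  P <- tryCatch(solve(params$Sigma), error = function(e) {
    solve(params$Sigma + diag(1e-10, 2))
  })
  n <- prep$n
  th <- matrix(NA_real_, n, 2)
  pc <- array(NA_real_, c(2, 2, n))
  for (g in prep$groups) {
    t_ <- g$times
    M <- matrix(c(length(t_), sum(t_), sum(t_), sum(t_^2)), 2, 2)
    A <- M / s2 + P
    Ainv <- solve(A)
    o <- group_offset(g, params$gamma, params$delta)
    R <- g$Y - rep(mu[1] + mu[2] * t_, each = nrow(g$Y)) - o
    cvec <- cbind(rowSums(R), R %*% t_)   # (S_r, S_rt) about the pop line
    # posterior mean of b - mu: Ainv %*% (c/s2) with c the residual stats
    bmat <- cvec %*% t(Ainv) / s2
    th[g$idx, 1] <- mu[1] + bmat[, 1]
    th[g$idx, 2] <- mu[2] + bmat[, 2]
    pc[, , g$idx] <- Ainv
  }
  out <- data.frame(id = prep$ids, theta0_hat = th[, 1],
                    theta1_hat = th[, 2], stringsAsFactors = FALSE)
  attr(out, "post_cov") <- pc
  if (!is.null(ids)) {
    keep <- match(ids, out$id)
    if (anyNA(keep)) stop("individual(s) absent from the fit")
    pc <- pc[, , keep, drop = FALSE]
    out <- out[keep, , drop = FALSE]
    attr(out, "post_cov") <- pc
  }
  out
}
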