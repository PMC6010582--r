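# Longitudinal sub-model: closed-form marginal likelihood, ML fitting,
# empirical-Bayes prediction.

test_that("marginal log-likelihood matches independent constructions", {
  co <- tiny_cohort()
  lp <- longitudinal_params(mu = c(4.6, 0.02),
                            Sigma = matrix(c(0.2, -0.004, -0.004, 0.002), 2),
                            sigma_e = 0.3, gamma = 0.05)
  # independent closed-form assembly
  expect_equal(lme_loglik(lp, co),
               brute_lme_loglik(lp$mu, lp$Sigma, lp$sigma_e, lp$gamma, co),
               tolerance = 1e-10)
  # single individual, single record: scalar normal with variance
  # (1,t) Sigma (1,t)' + sigma^2
  co1 <- cohort_data(data.frame(id = "u", time = 2, value = 5.1),
                     data.frame(id = "u", time = 4, status = 0),
                     genotypes = genotype_matrix(
                       matrix(1, 1, dimnames = list("s1", "u"))))
  v <- drop(c(1, 2) %*% lp$Sigma %*% c(1, 2)) + lp$sigma_e^2
  expect_equal(lme_loglik(lp, co1),
               dnorm(5.1, lp$mu[1] + 2 * lp$mu[2] + lp$gamma, sqrt(v),
                     log = TRUE),
               tolerance = 1e-12)
  # quadrature oracle: integrate the random effects numerically
  gh <- pracma::gaussHermite(80)
  L <- t(chol(lp$Sigma))
  nodes <- expand.grid(x1 = gh$x, x2 = gh$x)
  w <- as.vector(outer(gh$w, gh$w)) / pi
  ll_q <- 0
  for (id in c("a", "b", "c")) {
    rows <- co$longitudinal$id == id
    t_ <- co$longitudinal$time[rows]; y_ <- co$longitudinal$value[rows]
    zi <- co$genotypes$dosage[1, id]
    dens <- vapply(seq_len(nrow(nodes)), function(q) {
      b <- lp$mu + sqrt(2) * drop(L %*% c(nodes$x1[q], nodes$x2[q]))
      exp(sum(dnorm(y_, b[1] + b[2] * t_ + lp$gamma * zi, lp$sigma_e,
                    log = TRUE)))
    }, numeric(1))
    ll_q <- ll_q + log(sum(w * dens))
  }
  expect_equal(lme_loglik(lp, co), ll_q, tolerance = 1e-8)
})

test_that("ML fit matches a brute-force multi-start optimizer on a tiny cohort", {
  set.seed(9)
  long <- data.frame(id = rep(c("a", "b", "c"), each = 2),
                     time = rep(c(0, 3), 3),
                     value = c(4.1, 4.4, 5.2, 5.1, 4.7, 5.0))
  surv <- data.frame(id = c("a", "b", "c"), time = rep(9, 3),
                     status = rep(0, 3))
  co <- cohort_data(long, surv)
  fit <- fit_lme(co, include_genotype = FALSE, se = FALSE)
  # brute force over (mu0, mu1, log sd0, log sd1, atanh rho, log sigma)
  obj <- function(par) {
    S <- diag(exp(par[3:4])) %*%
      matrix(c(1, tanh(par[5]), tanh(par[5]), 1), 2) %*%
      diag(exp(par[3:4]))
    z <- co$longitudinal
    ll <- 0
    for (id in unique(z$id)) {
      t_ <- z$time[z$id == id]; y_ <- z$value[z$id == id]
      Zt <- cbind(1, t_)
      V <- Zt %*% S %*% t(Zt) + diag(exp(2 * par[6]), length(t_))
      ll <- ll + mvn_logdens(y_, par[1] + par[2] * t_, V)
    }
    -ll
  }
  best <- Inf
  for (st in list(c(4.5, 0.05, log(0.3), log(0.05), 0, log(0.2)),
                  c(4.8, 0, log(0.5), log(0.01), 0.5, log(0.1)),
                  c(4.2, 0.1, log(0.1), log(0.1), -0.5, log(0.3)))) {
    o <- optim(st, obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
    o <- optim(o$par, obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  expect_equal(fit$loglik, -best, tolerance = 1e-5)
})

test_that("ML fit agrees with the nlme reference on a simulated cohort", {
  skip_if_not_installed("nlme")
  sim <- cached_sim(600, 424, 0.1)
  fit <- fit_lme(sim$cohort)
  d <- sim$cohort$longitudinal
  d$z <- variant_z <- sim$truth$z[match(d$id, sim$truth$id)]
  ref <- nlme::lme(value ~ time + z, random = ~ time | id, data = d,
                   method = "ML",
                   control = nlme::lmeControl(opt = "optim",
                                              maxIter = 300,
                                              msMaxIter = 300))
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$fixef),
               unname(nlme::fixef(ref)), tolerance = 1e-4)
  expect_true(fit$converged)
  # fitted loglik beats the generating parameters (MLE property)
  p <- sim$params
  gen <- longitudinal_params(p$mu, p$Sigma, p$sigma_e, gamma = p$gamma)
  expect_gte(fit$loglik, lme_loglik(gen, sim$cohort))
  # estimated covariance stays PSD by construction
  expect_gte(min(eigen(fit$params$Sigma)$values), 0)
})

test_that("empirical-Bayes predictions shrink correctly", {
  sim <- cached_sim(600, 424, 0.1)
  fit <- fit_lme(sim$cohort)
  eb <- predict_random_effects(fit)
  # population average of posterior means tracks the population mean
  expect_equal(mean(eb$theta0_hat), fit$params$mu[1], tolerance = 0.02)
  expect_equal(mean(eb$theta1_hat), fit$params$mu[2], tolerance = 0.005)
  # individuals with one record are shrunk harder toward the population
  # line than individuals with four records
  nrec <- table(sim$cohort$longitudinal$id)[eb$id]
  ols_dev <- abs(eb$theta0_hat - fit$params$mu[1])
  expect_lt(mean(ols_dev[nrec == 1]), mean(ols_dev[nrec == 4]))
  # no-shrinkage limit: tiny error sd makes the posterior follow each
  # individual's own least-squares line
  lp <- fit$params
  lp$sigma_e <- 1e-6
  fit2 <- fit
  fit2$params <- lp
  eb2 <- predict_random_effects(fit2)
  full <- names(nrec)[nrec == 4][1:5]
  for (id in full) {
    rows <- sim$cohort$longitudinal$id == id
    t_ <- sim$cohort$longitudinal$time[rows]
    y_ <- sim$cohort$longitudinal$value[rows] -
      fit$params$gamma * sim$truth$z[sim$truth$id == id]
    ols <- coef(lm(y_ ~ t_))
    expect_equal(eb2$theta0_hat[eb2$id == id], unname(ols[1]),
                 tolerance = 1e-4)
    expect_equal(eb2$theta1_hat[eb2$id == id], unname(ols[2]),
                 tolerance = 1e-4)
  }
  expect_error(predict_random_effects(fit, ids = "nobody"), "absent")
})

test_that("singular designs and degenerate cohorts error cleanly", {
  long <- data.frame(id = c("a", "b"), time = c(0, 0), value = c(1, 2))
  surv <- data.frame(id = c("a", "b"), time = c(1, 1), status = c(0, 0))
  gm <- genotype_matrix(matrix(c(1, 1), 1, dimnames = list("s", c("a", "b"))))
  co <- cohort_data(long, surv, genotypes = gm)
  expect_error(fit_lme(co), "no variation")
})
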