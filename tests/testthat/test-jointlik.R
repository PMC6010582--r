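# Joint likelihood estimator: knot placement, adaptive-quadrature
# likelihood, maximum-likelihood fit, standard errors, Wald and LRT.

test_that("knots sit at event-time tertiles strictly inside follow-up", {
  surv <- data.frame(id = as.character(1:9), time = 1:9,
                     status = rep(1, 9))
  k <- choose_knots(surv)
  expect_equal(k, unname(quantile(1:9, c(1, 2) / 3)), tolerance = 1e-12)
  expect_true(k[1] > 0 && k[1] < k[2] && k[2] < 9)
  expect_error(choose_knots(data.frame(id = "a", time = 1, status = 1)),
               "at least 3")
  same <- data.frame(id = as.character(1:5), time = rep(4, 5),
                     status = rep(1, 5))
  expect_error(choose_knots(same), "degenerate")
})

test_that("adaptive-quadrature likelihood matches dense-grid integration", {
  co <- tiny_cohort()
  pl <- list(mu = c(4.6, 0.02),
             Sigma = matrix(c(0.2, -0.004, -0.004, 0.002), 2),
             sigma_e = 0.3, gamma = 0.05, delta = numeric(0),
             rates = c(0.01, 0.02, 0.015), beta = 1.2, alpha = 0.2,
             eta = numeric(0))
  knots <- c(3, 6)
  ll <- joint_loglik(pl, co, knots, quadrature_spec(9))
  ll_grid <- joint_grid_loglik(pl, co, knots)
  expect_equal(ll, ll_grid, tolerance = 1e-6)
  # a second parameter point, well away from the first (baseline rates
  # rescaled so the hazard stays of realistic size at the larger beta)
  pl2 <- pl; pl2$beta <- 3; pl2$alpha <- -0.4; pl2$sigma_e <- 0.4
  pl2$rates <- c(1e-8, 2e-8, 1.5e-8)
  expect_equal(joint_loglik(pl2, co, knots, quadrature_spec(9)),
               joint_grid_loglik(pl2, co, knots), tolerance = 1e-6)
})

test_that("compiled and reference likelihood implementations agree", {
  sim <- cached_sim(600, 424, 0.1)
  knots <- choose_knots(sim$cohort$survival)
  prep <- jmsnp:::prep_joint_data(sim$cohort, knots)
  p <- sim$params
  pl <- list(mu = p$mu, Sigma = p$Sigma, sigma_e = p$sigma_e,
             gamma = p$gamma, delta = numeric(0),
             rates = rep(p$lambda0, 3), beta = p$beta, alpha = p$alpha,
             eta = numeric(0))
  quad <- quadrature_spec(5)
  vR <- jmsnp:::joint_loglik_prep(pl, prep, quad, use_cpp = FALSE)
  prep$env <- NULL   # disable warm start for a pure comparison
  vC <- jmsnp:::joint_loglik_prep(pl, prep, quad, use_cpp = TRUE)
  expect_equal(vC, vR, tolerance = 1e-9)
})

test_that("beta = 0 factorizes the likelihood exactly at any quadrature", {
  co <- tiny_cohort()
  knots <- c(3, 6)
  pl <- list(mu = c(4.6, 0.02),
             Sigma = matrix(c(0.2, -0.004, -0.004, 0.002), 2),
             sigma_e = 0.3, gamma = 0.05, delta = numeric(0),
             rates = c(0.01, 0.02, 0.015), beta = 0, alpha = 0.2,
             eta = numeric(0))
  lp <- longitudinal_params(pl$mu, pl$Sigma, pl$sigma_e, gamma = pl$gamma)
  z <- c(0, 1, 2)
  target <- lme_loglik(lp, co) +
    piecewise_surv_loglik(pl$rates, pl$alpha, co$survival, z, knots)
  for (pts in c(3, 5, 9)) {
    expect_equal(joint_loglik(pl, co, knots, quadrature_spec(pts)), target,
                 tolerance = 1e-10)
  }
})

test_that("quadrature refinement has converged at the default order", {
  sim <- cached_sim(200, 910, 0.1)
  knots <- choose_knots(sim$cohort$survival)
  p <- sim$params
  pl <- list(mu = p$mu, Sigma = p$Sigma, sigma_e = p$sigma_e,
             gamma = p$gamma, delta = numeric(0),
             rates = rep(p$lambda0, 3), beta = p$beta, alpha = p$alpha,
             eta = numeric(0))
  l5 <- joint_loglik(pl, sim$cohort, knots, quadrature_spec(5))
  l15 <- joint_loglik(pl, sim$cohort, knots, quadrature_spec(15))
  expect_lt(abs(l5 - l15), 1e-4)
})

test_that("fitting data simulated at beta = 0 matches the separate fits", {
  p <- desir_defaults()
  p$beta <- 0
  p$d <- 0.1
  p$lambda0 <- NA_real_
  sim <- simulate_cohort(scenario_spec(4, 500, 0.244, 0.1), p, seed = 321)
  co <- sim$cohort
  knots <- choose_knots(co$survival)
  jf <- fit_joint(co, baseline = baseline_spec(knots),
                  fixed = c(beta = 0))
  expect_true(jf$converged)
  # separate longitudinal fit
  lf <- fit_lme(co, se = FALSE)
  expect_equal(unname(jf$estimates["gamma"]), unname(lf$fixef["gamma"]),
               tolerance = 1e-3)
  expect_equal(unname(jf$estimates["mu0"]), unname(lf$fixef["mu0"]),
               tolerance = 1e-3)
  expect_equal(unname(jf$estimates["mu1"]), unname(lf$fixef["mu1"]),
               tolerance = 1e-3)
  expect_equal(unname(jf$estimates["sigma_e"]), lf$params$sigma_e,
               tolerance = 1e-3)
  # separate piecewise-exponential survival fit (brute-force optimizer)
  z <- sim$truth$z
  o <- optim(c(log(0.01), log(0.01), log(0.01), 0), function(par) {
    -piecewise_surv_loglik(exp(par[1:3]), par[4], co$survival, z, knots)
  }, method = "BFGS", control = list(maxit = 1000, reltol = 1e-14))
  expect_equal(unname(jf$estimates["alpha"]), o$par[4], tolerance = 1e-3)
  expect_equal(unname(log(jf$estimates[c("lambda1", "lambda2", "lambda3")])),
               o$par[1:3], tolerance = 1e-2)
  # joint loglik equals the sum of the separate maxima
  expect_equal(jf$loglik, lf$loglik - o$value, tolerance = 1e-4)
})

test_that("the fitted likelihood dominates the generating parameters", {
  sim <- cached_sim(600, 424, 0.1)
  jf <- fit_joint(sim$cohort)
  expect_true(jf$converged)
  p <- sim$params
  gen <- list(mu = p$mu, Sigma = p$Sigma, sigma_e = p$sigma_e,
              gamma = p$gamma, delta = numeric(0),
              rates = rep(p$lambda0, 3), beta = p$beta, alpha = p$alpha,
              eta = numeric(0))
  ll_gen <- joint_loglik(gen, sim$cohort, jf$knots, jf$quad)
  expect_gte(jf$loglik, ll_gen)
})

test_that("standard errors are positive, finite and factorize at beta = 0", {
  p <- desir_defaults()
  p$beta <- 0
  p$d <- 0.1
  p$lambda0 <- NA_real_
  sim <- simulate_cohort(scenario_spec(4, 400, 0.244, 0.1), p, seed = 99)
  jf <- fit_joint(sim$cohort, fixed = c(beta = 0), se = TRUE)
  expect_true(jf$se_ok)
  keep <- c("gamma", "alpha", "mu0", "mu1", "sigma_e")
  expect_true(all(is.finite(jf$se[keep]) & jf$se[keep] > 0))
  lf <- fit_lme(sim$cohort)
  expect_equal(unname(jf$se["gamma"]), unname(lf$se["gamma"]),
               tolerance = 0.1 * unname(lf$se["gamma"]))
})

test_that("Wald tests behave as normal-theory tests", {
  fit <- structure(list(estimates = c(beta = 0, alpha = 1.96),
                        se = c(beta = 0.5, alpha = 1)),
                   class = "joint_fit")
  w <- wald_tests(fit)
  expect_equal(w$p[w$parameter == "beta"], 1)
  expect_equal(w$p[w$parameter == "alpha"], 0.05, tolerance = 1e-3)
  fit$estimates["alpha"] <- -1.96
  w2 <- wald_tests(fit)
  expect_equal(w2$p[w2$parameter == "alpha"],
               w$p[w$parameter == "alpha"])
})

test_that("the SNP likelihood-ratio test is non-negative with chi-square df 1", {
  sim <- cached_sim(600, 424, 0.1)
  lrt <- lrt_snp_effect(sim$cohort)
  expect_gte(lrt$statistic, 0)
  expect_equal(lrt$df, 1L)
  expect_equal(lrt$p,
               pchisq(lrt$statistic, 1, lower.tail = FALSE))
  expect_lte(lrt$reduced$loglik, lrt$full$loglik + 1e-6)
})

test_that("a cohort without events cannot identify the survival part", {
  long <- data.frame(id = rep(c("a", "b", "c"), each = 2),
                     time = rep(c(0, 3), 3),
                     value = c(4.1, 4.2, 4.9, 5.1, 4.6, 4.5))
  surv <- data.frame(id = c("a", "b", "c"), time = rep(9, 3),
                     status = rep(0, 3))
  gm <- genotype_matrix(matrix(c(0, 1, 2), 1,
                               dimnames = list("s1", c("a", "b", "c"))))
  co <- cohort_data(long, surv, genotypes = gm)
  expect_error(fit_joint(co), "unidentifiable")
})
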