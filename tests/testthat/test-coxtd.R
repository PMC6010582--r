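# Cox machinery: LOCF episodes, coxph-backed comparator, exact
# functional partial likelihood.

test_that("LOCF episodes carry the last measurement forward", {
  long <- data.frame(id = c("a", "a", "b"), time = c(0, 3, 0),
                     value = c(5.0, 5.5, 4.8))
  surv <- data.frame(id = c("a", "b"), time = c(5, 9), status = c(1, 0))
  co <- cohort_data(long, surv)
  ep <- build_locf_episodes(co)
  epa <- ep[ep$id == "a", ]
  expect_equal(epa$start, c(0, 3))
  expect_equal(epa$stop, c(3, 5))
  expect_equal(epa$value, c(5.0, 5.5))
  expect_equal(epa$status, c(0, 1))
  epb <- ep[ep$id == "b", ]
  expect_equal(nrow(epb), 1L)
  expect_equal(c(epb$start, epb$stop), c(0, 9))
  # episode stops partition (0, t_obs]
  stops <- tapply(ep$stop, ep$id, max)
  expect_equal(as.numeric(stops[surv$id]), surv$time)
})

test_that("partial-likelihood estimates match a brute-force maximizer", {
  surv <- data.frame(id = c("a", "b", "c"), time = c(2, 1, 3),
                     status = c(1, 1, 1))
  x <- c(1, 0, 0)
  covfun <- lapply(x, function(v) function(t) v)
  fit <- fit_cox_functional(surv, intercept = x, slope = rep(0, 3))
  grid <- seq(-5, 5, by = 1e-4)
  ll <- vapply(grid, function(b) brute_cox_loglik(b, surv, covfun),
               numeric(1))
  expect_equal(unname(fit$coefficients["beta"]), grid[which.max(ll)],
               tolerance = 1e-3)
  expect_lt(fit$score_norm, 1e-6)
  expect_gte(fit$loglik, brute_cox_loglik(0, surv, covfun))
})

test_that("functional fit agrees with brute force on small time-varying data", {
  set.seed(21)
  n <- 5
  surv <- data.frame(id = letters[1:n],
                     time = c(2.5, 4, 5.5, 7, 9),
                     status = c(1, 1, 0, 1, 0))
  a <- rnorm(n, 4.5, 0.3); s <- rnorm(n, 0.01, 0.03); z <- c(0, 1, 2, 1, 0)
  fit <- fit_cox_functional(surv, a, s, z = z)
  covfun <- lapply(1:n, function(i) {
    function(t) c(a[i] + s[i] * t, z[i])
  })
  o <- optim(c(0, 0), function(th) -brute_cox_loglik(th, surv, covfun),
             method = "BFGS", control = list(reltol = 1e-14))
  expect_equal(unname(fit$coefficients), o$par, tolerance = 1e-5)
  expect_equal(fit$loglik, -o$value, tolerance = 1e-8)
})

test_that("constant trajectories reduce the functional fit to coxph episodes", {
  sim <- cached_sim(600, 424, 0.1)
  surv <- sim$cohort$survival
  set.seed(31)
  x <- rnorm(nrow(surv), 4.5, 0.4)
  z <- sim$truth$z
  fit_f <- fit_cox_functional(surv, intercept = x, slope = rep(0, nrow(surv)),
                              z = z)
  ep <- data.frame(id = surv$id, start = 0, stop = surv$time,
                   status = surv$status, value = x)
  fit_e <- fit_cox(ep, data.frame(id = surv$id, z = z))
  expect_equal(fit_f$coefficients, fit_e$coefficients, tolerance = 1e-6)
  expect_equal(fit_f$loglik, fit_e$loglik, tolerance = 1e-6)
})

test_that("episode subdivision at non-event times changes nothing", {
  sim <- cached_sim(600, 424, 0.1)
  ep <- build_locf_episodes(sim$cohort)
  zdf <- data.frame(id = sim$cohort$survival$id, z = sim$truth$z)
  f1 <- fit_cox(ep, zdf)
  # split every episode longer than 1.7 years at a non-event point
  split_rows <- function(e) {
    if (e$stop - e$start > 1.7) {
      mid <- e$start + 0.617 * (e$stop - e$start)
      rbind(data.frame(id = e$id, start = e$start, stop = mid, status = 0,
                       value = e$value),
            data.frame(id = e$id, start = mid, stop = e$stop,
                       status = e$status, value = e$value))
    } else {
      e
    }
  }
  ep2 <- do.call(rbind, lapply(seq_len(nrow(ep)),
                               function(i) split_rows(ep[i, ])))
  f2 <- fit_cox(ep2, zdf)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
})

test_that("degenerate inputs are flagged rather than silently fitted", {
  surv <- data.frame(id = c("a", "b"), time = c(1, 2), status = c(0, 0))
  expect_error(fit_cox_functional(surv, c(1, 1), c(0, 0)), "no events")
  # constant covariate: no information
  surv2 <- data.frame(id = letters[1:4], time = 1:4,
                      status = c(1, 1, 1, 0))
  ep <- data.frame(id = surv2$id, start = 0, stop = surv2$time,
                   status = surv2$status, value = 1)
  f <- fit_cox(ep)
  expect_true(length(f$flagged) > 0 || is.na(f$coefficients["beta"]) ||
                !f$converged)
})

test_that("null simulation recovers a zero effect", {
  p <- desir_defaults()
  p$gamma <- 0; p$alpha <- 0
  p$lambda0 <- NA_real_
  sim <- simulate_cohort(scenario_spec(4, 3000, 0.25, 0.1), p, seed = 88)
  tr <- sim$truth
  fit <- fit_cox_functional(sim$cohort$survival, tr$theta0, tr$theta1,
                            z = tr$z)
  expect_lt(abs(fit$coefficients["alpha"]),
            3 * fit$se["alpha"])
})
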