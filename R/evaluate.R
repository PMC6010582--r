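# Simulation-study harness: run the joint model (JM), the two-step
# approximation (TS) and the extended Cox comparator over scenario grids,
# and summarize RMSE, bias, variance, rejection rates and convergence
# failures per scenario x method x parameter.

#' Root-mean-square error decomposition
#'
#' `rmse = sqrt(mean((est - truth)^2))`, `bias = mean(est) - truth`,
#' `variance = mean((est - mean(est))^2)` (mean squared deviation about
#' the replicate mean, so `rmse^2 = bias^2 + variance` holds exactly).
#' Non-finite estimates are dropped.
#'
#' @param estimates numeric vector of replicate estimates.
#' @param truth scalar generating value.
#' @return Named vector `rmse`, `bias`, `variance`, `n_used`.
#' @export
rmse_bias_variance <- function(estimates, truth) {
  est <- unname(estimates[is.finite(estimates)])
  truth <- unname(truth)
  if (!length(est)) stop("no finite estimates")
  m <- mean(est)
  c(rmse = sqrt(mean((est - truth)^2)),
    bias = m - truth,
    variance = mean((est - m)^2),
    n_used = length(est))
}

# fit one method to a simulated cohort; returns estimates, ses, p-values
# for (gamma, alpha, beta) plus a convergence flag
fit_one_method <- function(method, sim, quad, se = TRUE) {
  cohort <- sim$cohort
  if (method == "TS") {
    f <- fit_two_step(cohort)
    w <- wald_tests(f)
    list(est = f$estimates[c("gamma", "alpha", "beta")],
         p = stats::setNames(w$p[match(c("gamma", "alpha", "beta"),
                                       w$parameter)],
                             c("gamma", "alpha", "beta")),
         converged = f$converged)
  } else if (method == "Cox") {
    ep <- build_locf_episodes(cohort)
    zdf <- data.frame(id = cohort$survival$id,
                      z = variant_dosage(cohort, 1L),
                      stringsAsFactors = FALSE)
    f <- fit_cox(ep, zdf)
    w <- wald_tests(f)
    list(est = c(gamma = NA_real_,
                 alpha = unname(f$coefficients["alpha"]),
                 beta = unname(f$coefficients["beta"])),
         p = c(gamma = NA_real_,
               alpha = w$p[w$parameter == "alpha"],
               beta = w$p[w$parameter == "beta"]),
         converged = f$converged)
  } else if (method == "JM") {
    f <- fit_joint(cohort, quad = quad, se = se)
    if (se) {
      w <- wald_tests(f, c("gamma", "alpha", "beta"))
      p <- stats::setNames(w$p[match(c("gamma", "alpha", "beta"),
                                     w$parameter)],
                           c("gamma", "alpha", "beta"))
    } else {
      p <- c(gamma = NA_real_, alpha = NA_real_, beta = NA_real_)
    }
    list(est = f$estimates[c("gamma", "alpha", "beta")],
         p = p,
         converged = f$converged && (!se || isTRUE(f$se_ok)))
  } else {
    stop("unknown method: ", method)
  }
}

#' Run one simulation scenario
#'
#' Simulates `spec$n_replicates` cohorts (each method sees the same data
#' within a replicate, for paired comparison), fits the requested
#' methods, and records per-replicate estimates, Wald p-values and
#' convergence flags.  The baseline rate is calibrated once per scenario.
#' Non-converged replicates are excluded from the accuracy summaries but
#' reported through the convergence-failure rate, never dropped silently.
#'
#' @param spec A [scenario_spec()].
#' @param params A [generative_params()] template; `m`, `f`, `d` are
#'   overridden by the scenario.
#' @param methods subset of `c("JM", "TS", "Cox")`.
#' @param nominal_level rejection level for power / type-I error
#'   (default 0.05).
#' @param quad quadrature for JM fits.
#' @param se compute standard errors and Wald p-values (default `TRUE`);
#'   turning this off speeds up accuracy-only (RMSE) studies, whose
#'   rejection-rate column is then `NA`.
#' @return An object of class `scenario_result`: list with `spec`,
#'   `truth`, `replicates` (long data.frame of per-replicate estimates)
#'   and `summary` (see [summarize_scenario()]).
#' @export
run_scenario <- function(spec, params = desir_defaults(),
                         methods = c("JM", "TS", "Cox"),
                         nominal_level = 0.05,
                         quad = quadrature_spec(), se = TRUE) {
  stopifnot(inherits(spec, "scenario_spec"),
            all(methods %in% c("JM", "TS", "Cox")))
  params$m <- spec$m
  params$f <- spec$f
  params$d <- spec$d
  params$lambda0 <- NA_real_
  params$lambda0 <- calibrate_lambda(params)
  truth <- c(gamma = params$gamma, alpha = params$alpha, beta = params$beta)
  rows <- list()
  for (r in seq_len(spec$n_replicates)) {
    seed_r <- derive_seed(spec$base_seed, r)
    sim <- simulate_cohort(spec, params, seed = seed_r)
    for (meth in methods) {
      res <- tryCatch(fit_one_method(meth, sim, quad, se), error = function(e) {
        list(est = c(gamma = NA_real_, alpha = NA_real_, beta = NA_real_),
             p = c(gamma = NA_real_, alpha = NA_real_, beta = NA_real_),
             converged = FALSE)
      })
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, method = meth,
        parameter = c("gamma", "alpha", "beta"),
        estimate = unname(res$est[c("gamma", "alpha", "beta")]),
        p = unname(res$p[c("gamma", "alpha", "beta")]),
        converged = res$converged,
        stringsAsFactors = FALSE)
    }
  }
  reps <- do.call(rbind, rows)
  out <- structure(list(spec = spec, truth = truth, replicates = reps,
                        nominal_level = nominal_level),
                   class = "scenario_result")
  out$summary <- summarize_scenario(out)
  out
}

#' Summarize a scenario result
#'
#' @param result A [run_scenario()] result.
#' @return data.frame, one row per method x parameter: `rmse`, `bias`,
#'   `variance`, `rejection_rate` (share of converged replicates with
#'   Wald p below the nominal level), `n_converged`, `n_replicates`,
#'   `failure_rate`.
#' @export
summarize_scenario <- function(result) {
  reps <- result$replicates
  truth <- result$truth
  lvl <- result$nominal_level
  out <- list()
  for (meth in unique(reps$method)) {
    for (par in c("gamma", "alpha", "beta")) {
      rr <- reps[reps$method == meth & reps$parameter == par, , drop = FALSE]
      conv <- rr[rr$converged & is.finite(rr$estimate), , drop = FALSE]
      n_rep <- nrow(rr)
      if (nrow(conv)) {
        acc <- rmse_bias_variance(conv$estimate, truth[par])
        rej <- mean(conv$p < lvl, na.rm = TRUE)
      } else {
        acc <- c(rmse = NA_real_, bias = NA_real_, variance = NA_real_,
                 n_used = 0)
        rej <- NA_real_
      }
      out[[length(out) + 1L]] <- data.frame(
        m = result$spec$m, n = result$spec$n, f = result$spec$f,
        d = result$spec$d, method = meth, parameter = par,
        rmse = unname(acc["rmse"]), bias = unname(acc["bias"]),
        variance = unname(acc["variance"]),
        rejection_rate = rej,
        n_converged = as.integer(acc["n_used"]),
        n_replicates = n_rep,
        failure_rate = 1 - acc[["n_used"]] / n_rep,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, out)
  # parameters a method does not estimate (Cox has no gamma) are dropped
  df[!(df$method == "Cox" & df$parameter == "gamma"), , drop = FALSE]
}

#' Combine scenario results into one long table
#'
#' @param results list of [run_scenario()] results.
#' @return Tidy data.frame: scenario fields, method, parameter, rmse,
#'   bias, variance, rejection rate, convergence counts.
#' @export
compare_methods <- function(results) {
  if (!length(results)) stop("no scenario results")
  do.call(rbind, c(lapply(results, function(r) r$summary),
                   list(make.row.names = FALSE)))
}
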