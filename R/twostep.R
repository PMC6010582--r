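# The two-step (TS) estimator: fit the linear mixed model, plug each
# subject's empirical-Bayes trajectory into the Cox partial likelihood.

#' Fit the two-step (plug-in) estimator
#'
#' Stage 1 fits the longitudinal sub-model by maximum likelihood
#' ([fit_lme()]).  Stage 2 substitutes each subject's estimated
#' trajectory `X*_i(t) = theta0_hat_i + theta1_hat_i * t + gamma_hat *
#' z_i (+ delta_hat' W_i)` -- the empirical-Bayes posterior means plus
#' the fitted fixed effects -- into the Cox partial likelihood
#' ([fit_cox_functional()]) with the genotype as a separate covariate, so
#' `alpha` measures the residual direct genotype effect on the hazard.
#' Stage-2 standard errors are naive plug-in values: the uncertainty of
#' the stage-1 trajectory is not propagated, which is part of the
#' approximation under study.
#'
#' @param cohort A [cohort_data()].
#' @param include_genotype,include_covariates passed to both stages.
#' @param dosage optional dosage override (per-variant scan).
#' @param se compute standard errors.
#' @return An object of class `two_step_fit`: list with `lme` (the
#'   stage-1 [fit_lme()]), `cox` (the stage-2 `cox_fit`), and `estimates`
#'   / `se` named vectors over `gamma` (stage 1), `beta`, `alpha`
#'   (stage 2), plus `converged`.
#' @export
fit_two_step <- function(cohort, include_genotype = TRUE,
                         include_covariates = TRUE, dosage = NULL,
                         se = TRUE) {
  st1 <- tryCatch(
    fit_lme(cohort, include_genotype, include_covariates, dosage, se = se),
    error = function(e) stop("two-step stage 1 (LME) failed: ",
                             conditionMessage(e), call. = FALSE))
  eb <- predict_random_effects(st1)
  prep <- st1$prep
  o <- rep(0, prep$n)
  if (prep$has_geno) o <- o + st1$params$gamma * prep$z
  if (length(st1$params$delta)) {
    o <- o + drop(prep$W %*% st1$params$delta)
  }
  surv <- cohort$survival[match(prep$ids, cohort$survival$id), , drop = FALSE]
  st2 <- tryCatch(
    fit_cox_functional(surv,
                       intercept = eb$theta0_hat + o,
                       slope = eb$theta1_hat,
                       z = if (prep$has_geno) prep$z,
                       W = if (prep$n_cov) prep$W,
                       se = se),
    error = function(e) stop("two-step stage 2 (Cox) failed: ",
                             conditionMessage(e), call. = FALSE))
  est <- c(gamma = if (prep$has_geno) unname(st1$fixef["gamma"]) else NA_real_,
           beta = unname(st2$coefficients["beta"]),
           alpha = if (prep$has_geno) unname(st2$coefficients["alpha"]) else NA_real_)
  ses <- c(gamma = if (prep$has_geno) unname(st1$se["gamma"]) else NA_real_,
           beta = unname(st2$se["beta"]),
           alpha = if (prep$has_geno) unname(st2$se["alpha"]) else NA_real_)
  structure(list(lme = st1, cox = st2, estimates = est, se = ses,
                 converged = st1$converged && st2$converged),
            class = "two_step_fit")
}

#' @export
print.two_step_fit <- function(x, ...) {
  cat(sprintf("<two_step_fit> converged=%s\n", x$converged))
  print(round(data.frame(estimate = x$estimates, se = x$se), 5))
  invisible(x)
}

#' Wald tests for a fitted estimator
#'
#' Two-sided normal-reference Wald test `z = estimate / SE` for each
#' requested parameter of a fit that carries `estimates` and `se`
#' vectors (two-step fits) or `coefficients` (`cox_fit`) or the joint
#' model's parameter table.
#'
#' @param fit A `two_step_fit`, `cox_fit` or `joint_fit`.
#' @param parameters which parameters to test (default: all available).
#' @return data.frame `parameter`, `estimate`, `se`, `z`, `p`.
#' @export
wald_tests <- function(fit, parameters = NULL) {
  if (inherits(fit, "joint_fit")) {
    est <- fit$estimates; ses <- fit$se
  } else if (inherits(fit, "cox_fit")) {
    est <- fit$coefficients; ses <- fit$se
  } else {
    est <- fit$estimates; ses <- fit$se
  }
  if (is.null(parameters)) parameters <- names(est)
  parameters <- intersect(parameters, names(est))
  if (!length(parameters)) stop("no matching parameters with estimates")
  e <- est[parameters]; s <- ses[parameters]
  if (anyNA(s)) warning("missing standard error for some parameter(s)")
  z <- e / s
  data.frame(parameter = parameters, estimate = unname(e), se = unname(s),
             z = unname(z), p = unname(2 * stats::pnorm(-abs(z))),
             stringsAsFactors = FALSE, row.names = NULL)
}
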