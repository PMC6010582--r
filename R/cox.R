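# Cox proportional-hazards machinery with time-varying covariates:
#  * build_locf_episodes + fit_cox: the extended-Cox comparator, with the
#    observed biomarker carried forward over counting-process episodes
#    (fitted through survival::coxph, Breslow ties);
#  * fit_cox_functional: Breslow partial likelihood with each subject's
#    affine trajectory evaluated *exactly* at every event time, maximized
#    by Newton-Raphson.  Used by the two-step estimator and by oracle fits
#    on the true simulated trajectories.
# Risk sets use half-open episodes (start, stop]: an individual is at risk
# at t iff start < t <= stop.

#' Build last-observation-carried-forward episodes
#'
#' Counting-process layout for the extended Cox model: the covariate
#' value on `(t_j, t_{j+1}]` is the measurement taken at `t_j`, and the
#' final episode extends to the observed survival time.  A measurement
#' taken exactly at the observed time opens no episode.
#'
#' @param cohort A [cohort_data()].
#' @return data.frame `id`, `start`, `stop`, `status` (1 only on an
#'   individual's final episode if their event occurred), `value`.
#' @export
build_locf_episodes <- function(cohort) {
  long <- cohort$longitudinal
  surv <- cohort$survival
  sp_t <- split(long$time, long$id)
  sp_y <- split(long$value, long$id)
  out <- vector("list", nrow(surv))
  for (i in seq_len(nrow(surv))) {
    id <- surv$id[i]; tobs <- surv$time[i]
    t_ <- sp_t[[id]]; y_ <- sp_y[[id]]
    if (is.null(t_) || t_[1] > 0) {
      stop(sprintf("individual %s has no baseline (t=0) measurement", id))
    }
    keep <- t_ < tobs - 1e-12
    t_ <- t_[keep]; y_ <- y_[keep]
    stops <- c(t_[-1], tobs)
    out[[i]] <- data.frame(id = id, start = t_, stop = stops,
                           status = c(rep(0, length(t_) - 1), surv$status[i]),
                           value = y_, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

cox_fit_obj <- function(coefficients, se, vcov, loglik, loglik0, converged,
                        n, n_events, score_norm = NA_real_,
                        flagged = character(0)) {
  structure(list(coefficients = coefficients, se = se, vcov = vcov,
                 loglik = loglik, loglik0 = loglik0, converged = converged,
                 n = n, n_events = n_events, score_norm = score_norm,
                 flagged = flagged),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n=%d, events=%d, partial logLik=%.3f, converged=%s\n",
              x$n, x$n_events, x$loglik, x$converged))
  print(round(data.frame(estimate = x$coefficients, se = x$se), 5))
  if (length(x$flagged)) cat("  flagged:", paste(x$flagged, collapse = "; "), "\n")
  invisible(x)
}

#' Fit the extended Cox model on an episode table
#'
#' Breslow partial-likelihood fit over counting-process episodes, via
#' `survival::coxph`.  The biomarker coefficient is reported as `beta`,
#' the genotype coefficient (column `z` of `static_covariates`) as
#' `alpha`, any further static covariates under their own names.
#'
#' @param episodes data.frame from [build_locf_episodes()] (columns `id`,
#'   `start`, `stop`, `status`, `value`).
#' @param static_covariates optional data.frame with column `id` plus
#'   per-individual covariates (e.g. `z` = dosage), merged onto episodes.
#' @return A `cox_fit`.  A covariate with no information (e.g. constant
#'   across individuals) leaves its coefficient `NA` and is listed in
#'   `flagged`; monotone-likelihood problems are flagged too.
#' @export
fit_cox <- function(episodes, static_covariates = NULL) {
  stopifnot(all(c("id", "start", "stop", "status", "value") %in%
                  names(episodes)))
  if (sum(episodes$status) == 0) stop("no events")
  df <- episodes
  extra <- character(0)
  if (!is.null(static_covariates)) {
    stopifnot("id" %in% names(static_covariates))
    extra <- setdiff(names(static_covariates), "id")
    df <- cbind(df, static_covariates[match(df$id, static_covariates$id),
                                      extra, drop = FALSE])
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(start, stop, status) ~",
    paste(c("value", extra), collapse = " + ")))
  flagged <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "breslow",
                    control = survival::coxph.control(eps = 1e-10,
                                                      iter.max = 50)),
    warning = function(w) {
      flagged <<- c(flagged, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  cf <- stats::coef(fit)
  rename <- function(nm) {
    nm[nm == "value"] <- "beta"
    nm[nm == "z"] <- "alpha"
    nm
  }
  names(cf) <- rename(names(cf))
  se <- sqrt(diag(fit$var))
  names(se) <- names(cf)
  if (anyNA(cf)) {
    flagged <- c(flagged,
                 paste("no information for:",
                       paste(names(cf)[is.na(cf)], collapse = ", ")))
    se[is.na(cf)] <- Inf
  }
  V <- fit$var
  dimnames(V) <- list(names(cf), names(cf))
  cox_fit_obj(cf, se, V,
              loglik = fit$loglik[2], loglik0 = fit$loglik[1],
              converged = !anyNA(cf) &&
                !any(grepl("infinite|ran out of iterations", flagged)),
              n = length(unique(df$id)), n_events = sum(df$status),
              flagged = flagged)
}

#' Cox partial likelihood with exact affine trajectories
#'
#' Fits the hazard `lambda0(t) exp(beta * X_i(t) + alpha * z_i + eta' W_i)`
#' by Breslow partial likelihood, where each subject's time-varying
#' covariate is the affine function `X_i(t) = intercept_i + slope_i * t`,
#' evaluated exactly at every event time rather than carried forward in
#' steps.  Maximized by Newton-Raphson with step halving.
#'
#' @param surv data.frame `id`, `time`, `status` (one row per individual).
#' @param intercept,slope per-individual trajectory coefficients, aligned
#'   with `surv`.
#' @param z optional per-individual dosage (adds the `alpha` term).
#' @param W optional numeric matrix of per-individual covariates.
#' @param se compute standard errors from the inverse observed
#'   information of the partial likelihood.
#' @param tol convergence tolerance on the score (default 1e-9).
#' @return A `cox_fit` with coefficients `beta` (trajectory), `alpha`
#'   (genotype, when `z` given) and one entry per column of `W`.
#' @export
fit_cox_functional <- function(surv, intercept, slope, z = NULL, W = NULL,
                               se = TRUE, tol = 1e-9) {
  n <- nrow(surv)
  stopifnot(length(intercept) == n, length(slope) == n)
  if (sum(surv$status) == 0) stop("no events")
  Xs <- cbind(if (!is.null(z)) as.numeric(z),
              if (!is.null(W)) as.matrix(W))
  p_s <- if (is.null(Xs)) 0L else ncol(Xs)
  nm <- c("beta",
          if (!is.null(z)) "alpha",
          if (!is.null(W)) colnames(as.matrix(W)) %||% paste0("eta", seq_len(ncol(as.matrix(W)))))
  p <- 1L + p_s

  ord <- order(-surv$time)              # decreasing observed time
  tobs <- surv$time[ord]
  status <- surv$status[ord]
  a <- intercept[ord]; s_ <- slope[ord]
  if (p_s) Xs <- Xs[ord, , drop = FALSE]

  ev_times <- sort(unique(surv$time[surv$status == 1]))
  D <- length(ev_times)
  # risk-set prefix size and event membership per unique time
  n_at_risk <- vapply(ev_times, function(e) sum(tobs >= e - 1e-12), integer(1))
  ev_idx <- lapply(ev_times, function(e) {
    which(abs(tobs - e) < 1e-12 & status == 1)
  })

  Xs_m <- if (p_s) Xs else matrix(0, n, 0)
  objective <- function(th) {
    res <- cox_pl_cpp(th, a, s_, Xs_m, ev_times, n_at_risk, ev_idx, TRUE)
    list(ll = res$ll, U = drop(res$U), I = res$I)
  }

  th <- numeric(p)
  ob <- objective(th)
  flagged <- character(0)
  converged <- FALSE
  for (it in 1:50) {
    step <- tryCatch(solve(ob$I, ob$U), error = function(e) NULL)
    if (is.null(step)) {
      flagged <- c(flagged, "singular information (no information for some covariate)")
      break
    }
    # step halving if the partial likelihood does not improve
    lam <- 1
    repeat {
      th_new <- th + lam * step
      ob_new <- objective(th_new)
      if (is.finite(ob_new$ll) && ob_new$ll >= ob$ll - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-8) break
    }
    th <- th_new; ob <- ob_new
    # converge on the score, or on a step at the rounding floor of the
    # score computation (large risk-set sums cannot drive the score
    # below their accumulation noise)
    if (max(abs(ob$U)) < max(tol, 1e-9) ||
        max(abs(lam * step)) < 1e-10) { converged <- TRUE; break }
  }
  score_norm <- sqrt(sum(ob$U^2))
  if (!converged && score_norm < 1e-6) converged <- TRUE
  if (!converged) flagged <- c(flagged, "Newton-Raphson did not converge")
  if (any(abs(th) > 15)) {
    flagged <- c(flagged,
                 "extreme coefficient: possibly monotone partial likelihood")
  }
  names(th) <- nm
  V <- matrix(NA_real_, p, p, dimnames = list(nm, nm))
  ses <- stats::setNames(rep(NA_real_, p), nm)
  if (se) {
    V_try <- tryCatch(solve(ob$I), error = function(e) NULL)
    if (!is.null(V_try)) {
      V <- V_try; dimnames(V) <- list(nm, nm)
      ses <- stats::setNames(sqrt(pmax(diag(V_try), 0)), nm)
    }
  }
  ll0 <- objective(numeric(p))$ll
  cox_fit_obj(th, ses, V, loglik = ob$ll, loglik0 = ll0,
              converged = converged, n = n, n_events = sum(surv$status),
              score_norm = score_norm, flagged = flagged)
}
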