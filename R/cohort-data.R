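#' Assemble and validate an analysis-ready cohort
#'
#' Bundles the three tables a joint longitudinal/survival analysis needs:
#' a long-format table of repeated biomarker measurements, a one-row-per
#' individual survival table, and (optionally) genotype dosages and
#' baseline covariates.  All cross-table consistency rules are enforced at
#' construction time so downstream fitting code can assume a clean cohort.
#'
#' Invariants checked:
#' * every individual has at least one longitudinal record and exactly one
#'   survival record, and the id sets agree;
#' * measurement times are non-negative, finite and strictly increasing
#'   within individual;
#' * no measurement occurs after the individual's observed survival time
#'   (biomarker collection stops at the event -- event-driven dropout);
#' * observed times are positive and event indicators are 0/1;
#' * genotype dosages, when present, lie in `[0, 2]` or are missing.
#'
#' @param longitudinal data.frame with columns `id`, `time` (years since
#'   baseline), `value` (biomarker level, e.g. mmol/L for fasting glucose).
#' @param survival data.frame with columns `id`, `time` (observed time:
#'   the event time or the censoring time, whichever came first, in
#'   years) and `status` (1 = event, 0 = censored).
#' @param genotypes optional [genotype_matrix()].
#' @param covariates optional data.frame with column `id` plus numeric
#'   baseline covariates, one row per individual.
#' @return An object of class `cohort_data`: a list with elements
#'   `longitudinal`, `survival`, `genotypes`, `covariates`.
#' @export
cohort_data <- function(longitudinal, survival, genotypes = NULL,
                        covariates = NULL) {
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stop(sprintf("%s table is missing column(s): %s", what,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  stopifnot(is.data.frame(longitudinal), is.data.frame(survival))
  need(longitudinal, c("id", "time", "value"), "longitudinal")
  need(survival, c("id", "time", "status"), "survival")
  if (nrow(survival) == 0L) stop("no survival records", call. = FALSE)
  if (nrow(longitudinal) == 0L) stop("no longitudinal records", call. = FALSE)

  long <- data.frame(id = as.character(longitudinal$id),
                     time = as.numeric(longitudinal$time),
                     value = as.numeric(longitudinal$value),
                     stringsAsFactors = FALSE)
  surv <- data.frame(id = as.character(survival$id),
                     time = as.numeric(survival$time),
                     status = as.numeric(survival$status),
                     stringsAsFactors = FALSE)
  if (anyNA(long$time) || anyNA(long$value)) {
    stop("non-numeric or missing entries in longitudinal table", call. = FALSE)
  }
  if (anyNA(surv$time) || anyNA(surv$status)) {
    stop("non-numeric or missing entries in survival table", call. = FALSE)
  }
  if (anyDuplicated(surv$id)) {
    stop("survival table has more than one row for some individual(s)",
         call. = FALSE)
  }
  if (!all(surv$status %in% c(0, 1))) {
    stop("event indicator must be 0 or 1", call. = FALSE)
  }
  if (any(surv$time <= 0)) {
    stop("observed survival times must be positive", call. = FALSE)
  }
  if (any(long$time < 0) || any(!is.finite(long$value))) {
    stop("measurement times must be >= 0 and values finite", call. = FALSE)
  }

  only_long <- setdiff(unique(long$id), surv$id)
  only_surv <- setdiff(surv$id, unique(long$id))
  if (length(only_long) || length(only_surv)) {
    stop(sprintf(
      "id mismatch between tables (%d only longitudinal, %d only survival)",
      length(only_long), length(only_surv)), call. = FALSE)
  }

  ord <- order(long$id, long$time)
  long <- long[ord, , drop = FALSE]
  dup <- stats::ave(long$time, long$id,
                    FUN = function(t) c(FALSE, diff(t) <= 0))
  if (any(dup > 0)) {
    stop("measurement times must be strictly increasing within individual",
         call. = FALSE)
  }

  tobs <- surv$time[match(long$id, surv$id)]
  bad <- which(long$time > tobs + 1e-12)
  if (length(bad)) {
    msg <- paste(sprintf("id %s at t=%g (observed time %g)",
                         long$id[bad], long$time[bad], tobs[bad]),
                 collapse = "; ")
    stop("longitudinal record(s) after the observed survival time: ", msg,
         call. = FALSE)
  }

  if (!is.null(genotypes)) {
    stopifnot(inherits(genotypes, "genotype_matrix"))
    unknown <- setdiff(colnames(genotypes$dosage), surv$id)
    if (length(unknown)) {
      stop(sprintf("genotype matrix has %d individual(s) absent from the cohort",
                   length(unknown)), call. = FALSE)
    }
  }
  if (!is.null(covariates)) {
    stopifnot(is.data.frame(covariates))
    need(covariates, "id", "covariate")
    covariates$id <- as.character(covariates$id)
    if (anyDuplicated(covariates$id)) {
      stop("covariate table must have one row per individual", call. = FALSE)
    }
    num <- covariates[setdiff(names(covariates), "id")]
    if (anyNA(num) || !all(vapply(num, is.numeric, logical(1)))) {
      stop("covariates must be numeric with no missing values after encoding",
           call. = FALSE)
    }
  }

  structure(list(longitudinal = long, survival = surv,
                 genotypes = genotypes, covariates = covariates),
            class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  cat(sprintf("<cohort_data> %d individuals, %d measurements, %d events\n",
              nrow(x$survival), nrow(x$longitudinal),
              sum(x$survival$status)))
  if (!is.null(x$genotypes)) {
    cat(sprintf("  genotypes: %d variant(s)\n", nrow(x$genotypes$dosage)))
  }
  if (!is.null(x$covariates)) {
    cat(sprintf("  covariates: %s\n",
                paste(setdiff(names(x$covariates), "id"), collapse = ", ")))
  }
  invisible(x)
}

#' Number of individuals in a cohort
#' @param cohort A [cohort_data()] object.
#' @return Integer count.
#' @export
n_individuals <- function(cohort) nrow(cohort$survival)

#' Construct a genotype dosage matrix
#'
#' @param dosage numeric matrix, variants in rows and individuals in
#'   columns, additive effect-allele dosages in `[0, 2]` (`NA` = missing).
#'   Row names are variant ids, column names individual ids.
#' @param effect_allele character vector of per-variant effect-allele
#'   labels (the allele whose copies the dosage counts).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, effect_allele = NULL) {
  stopifnot(is.matrix(dosage))
  if (nrow(dosage) > 0 && is.null(rownames(dosage))) {
    rownames(dosage) <- paste0("var", seq_len(nrow(dosage)))
  }
  if (is.null(colnames(dosage))) {
    stop("dosage matrix must carry individual ids as column names")
  }
  storage.mode(dosage) <- "double"
  if (length(dosage) && any(!is.na(dosage))) {
    rng <- range(dosage, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 2) {
      stop(sprintf("dosage outside [0, 2] (range %.3g..%.3g)", rng[1], rng[2]))
    }
  }
  if (is.null(effect_allele)) effect_allele <- rep("ALT", nrow(dosage))
  stopifnot(length(effect_allele) == nrow(dosage))
  structure(list(dosage = dosage,
                 effect_allele = as.character(effect_allele)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d variant(s) x %d individual(s), %.1f%% missing\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

# dosage vector for one variant, aligned to the cohort's individuals
variant_dosage <- function(cohort, variant = 1L) {
  gm <- cohort$genotypes
  if (is.null(gm)) stop("cohort carries no genotypes")
  z <- gm$dosage[variant, , drop = TRUE]
  z[match(cohort$survival$id, colnames(gm$dosage))]
}

# covariate design matrix (0 columns when absent), aligned to individuals
covariate_matrix <- function(cohort) {
  ids <- cohort$survival$id
  if (is.null(cohort$covariates)) {
    return(matrix(0, nrow = length(ids), ncol = 0))
  }
  cv <- cohort$covariates
  W <- as.matrix(cv[match(ids, cv$id), setdiff(names(cv), "id"), drop = FALSE])
  rownames(W) <- ids
  W
}
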