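# Per-SNP association scan: the phenotype (longitudinal + survival) is
# fixed while each QC'd variant is tested one at a time, by the fast
# two-step estimator and/or the joint model.  A two-stage mode uses TS as
# a pre-filter and refits only promising variants with JM.

scan_row_na <- function(variant, ea, af, method, note) {
  data.frame(variant = variant, effect_allele = ea, eaf = af,
             method = method,
             gamma = NA_real_, gamma_se = NA_real_, gamma_p = NA_real_,
             alpha = NA_real_, alpha_se = NA_real_, alpha_p = NA_real_,
             beta = NA_real_, beta_se = NA_real_, beta_p = NA_real_,
             lrt_stat = NA_real_, lrt_p = NA_real_,
             converged = FALSE, note = note, stringsAsFactors = FALSE)
}

scan_one_variant <- function(cohort, z, variant, ea, method, quad,
                             with_lrt = FALSE) {
  af <- mean(z, na.rm = TRUE) / 2
  v <- stats::var(z, na.rm = TRUE)
  if (is.na(af) || is.na(v) || v == 0) {
    return(scan_row_na(variant, ea, af, method, "no variation"))
  }
  if (method == "TS") {
    f <- fit_two_step(cohort, dosage = z)
    w <- wald_tests(f)
    g <- w[w$parameter == "gamma", ]; a <- w[w$parameter == "alpha", ]
    b <- w[w$parameter == "beta", ]
    data.frame(variant = variant, effect_allele = ea, eaf = af,
               method = method,
               gamma = g$estimate, gamma_se = g$se, gamma_p = g$p,
               alpha = a$estimate, alpha_se = a$se, alpha_p = a$p,
               beta = b$estimate, beta_se = b$se, beta_p = b$p,
               lrt_stat = NA_real_, lrt_p = NA_real_,
               converged = f$converged, note = "", stringsAsFactors = FALSE)
  } else {
    f <- fit_joint(cohort, quad = quad, dosage = z, se = TRUE)
    w <- wald_tests(f, c("gamma", "alpha", "beta"))
    g <- w[w$parameter == "gamma", ]; a <- w[w$parameter == "alpha", ]
    b <- w[w$parameter == "beta", ]
    lrt <- if (with_lrt) {
      lrt_snp_effect(cohort, quad = quad, dosage = z, full = f)
    }
    data.frame(variant = variant, effect_allele = ea, eaf = af,
               method = method,
               gamma = g$estimate, gamma_se = g$se, gamma_p = g$p,
               alpha = a$estimate, alpha_se = a$se, alpha_p = a$p,
               beta = b$estimate, beta_se = b$se, beta_p = b$p,
               lrt_stat = if (is.null(lrt)) NA_real_ else lrt$statistic,
               lrt_p = if (is.null(lrt)) NA_real_ else lrt$p,
               converged = f$converged, note = "", stringsAsFactors = FALSE)
  }
}

#' Per-SNP association scan
#'
#' Applies variant quality control, then fits the chosen estimator to
#' each surviving variant independently (the phenotype side of the model
#' is identical across variants).  Individuals with a missing dosage for
#' a variant are dropped from that variant's fit only.  Failures are
#' caught, flagged in the result and the scan continues.
#'
#' @param cohort A [cohort_data()] (its own genotype slot is ignored
#'   when `genotypes` is supplied).
#' @param genotypes A [genotype_matrix()] over the cohort's individuals.
#' @param method `"TS"` (fast) or `"JM"`.
#' @param qc apply [qc_filter_variants()] first (default `TRUE`).
#' @param qc_thresholds list with `call_rate_min`, `maf_min`,
#'   `hwe_p_min` overriding the QC defaults.
#' @param quad quadrature for JM fits.
#' @param with_lrt also compute the joint-SNP-effect likelihood-ratio
#'   test per variant (JM only).
#' @return data.frame, one row per variant: effect allele, allele
#'   frequency, estimates / SEs / Wald p-values for `gamma`, `alpha`,
#'   `beta`, optional LRT columns, convergence flag and note.  The
#'   Bonferroni threshold for the number of tested variants is attached
#'   as `attr(, "bonferroni")`.
#' @export
scan_variants <- function(cohort, genotypes, method = c("TS", "JM"),
                          qc = TRUE, qc_thresholds = list(),
                          quad = quadrature_spec(), with_lrt = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (qc) {
    th <- utils::modifyList(list(call_rate_min = 0.95, maf_min = 0.05,
                                 hwe_p_min = 1e-5), qc_thresholds)
    genotypes <- qc_filter_variants(genotypes, th$call_rate_min,
                                    th$maf_min, th$hwe_p_min)$genotypes
  }
  nv <- nrow(genotypes$dosage)
  if (nv == 0L) stop("zero variants after quality control")
  ids <- cohort$survival$id
  rows <- vector("list", nv)
  for (i in seq_len(nv)) {
    variant <- rownames(genotypes$dosage)[i]
    z <- genotypes$dosage[i, match(ids, colnames(genotypes$dosage))]
    rows[[i]] <- tryCatch(
      scan_one_variant(cohort, unname(z), variant,
                       genotypes$effect_allele[i], method, quad, with_lrt),
      error = function(e) {
        scan_row_na(variant, genotypes$effect_allele[i],
                    mean(z, na.rm = TRUE) / 2, method, conditionMessage(e))
      })
  }
  out <- do.call(rbind, rows)
  attr(out, "bonferroni") <- bonferroni_threshold(0.05, nv)
  out
}

#' Two-stage scan: TS pre-filter, JM refinement
#'
#' Runs the fast two-step estimator on every variant, then refits with
#' the joint model only those variants whose TS Wald test for the
#' trajectory effect (`gamma`) or the direct hazard effect (`alpha`)
#' passes the pre-filter threshold.  Rows from both stages are returned,
#' labelled by method; JM rows are numerically identical to what a full
#' JM scan would produce for the same variants.
#'
#' @param cohort,genotypes,qc,qc_thresholds,quad,with_lrt as in
#'   [scan_variants()].
#' @param prefilter_p pre-filter p-value threshold in `(0, 1]`; 1 refits
#'   every variant with JM, values near 0 refit none.
#' @return data.frame as in [scan_variants()] with rows for both stages.
#' @export
two_stage_scan <- function(cohort, genotypes, prefilter_p = 0.05,
                           qc = TRUE, qc_thresholds = list(),
                           quad = quadrature_spec(), with_lrt = FALSE) {
  stopifnot(prefilter_p > 0, prefilter_p <= 1)
  ts <- scan_variants(cohort, genotypes, method = "TS", qc = qc,
                      qc_thresholds = qc_thresholds, quad = quad)
  pass <- ts$variant[which(ts$gamma_p < prefilter_p |
                             ts$alpha_p < prefilter_p)]
  out <- ts
  if (length(pass)) {
    keep <- rownames(genotypes$dosage) %in% pass
    gm2 <- genotype_matrix(genotypes$dosage[keep, , drop = FALSE],
                           genotypes$effect_allele[keep])
    jm <- scan_variants(cohort, gm2, method = "JM", qc = FALSE,
                        quad = quad, with_lrt = with_lrt)
    out <- rbind(ts, jm)
  }
  attr(out, "bonferroni") <- attr(ts, "bonferroni")
  out
}
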