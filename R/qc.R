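# Variant-level quality control: call rate, minor allele frequency and the
# exact Hardy-Weinberg equilibrium test.

#' Exact Hardy-Weinberg equilibrium p-value
#'
#' Exact conditional test of Hardy-Weinberg genotype proportions: given
#' the observed allele counts, the probability of every possible
#' heterozygote count is computed under the HWE null, and the p-value is
#' the total probability of all heterozygote counts no more probable than
#' the observed one (two-sided by probability ordering, the standard
#' exact test).  Probabilities follow the hypergeometric-type recurrence,
#' which keeps the enumeration stable for thousands of individuals.
#'
#' @param n_AA,n_Aa,n_aa non-negative integer genotype counts
#'   (homozygous reference, heterozygous, homozygous alternative; the
#'   labelling of the two homozygote classes is irrelevant).
#' @return p-value in `(0, 1]`.  Monomorphic variants give exactly 1.
#' @export
hwe_exact_pvalue <- function(n_AA, n_Aa, n_aa) {
  stopifnot(length(n_AA) == 1, length(n_Aa) == 1, length(n_aa) == 1)
  if (anyNA(c(n_AA, n_Aa, n_aa)) || any(c(n_AA, n_Aa, n_aa) < 0)) {
    stop("genotype counts must be non-negative")
  }
  if (any(abs(c(n_AA, n_Aa, n_aa) - round(c(n_AA, n_Aa, n_aa))) > 1e-8)) {
    stop("genotype counts must be integers")
  }
  n_AA <- round(n_AA); n_Aa <- round(n_Aa); n_aa <- round(n_aa)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("no genotyped individuals (all calls missing)")

  rare <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)   # minor allele count
  if (rare == 0) return(1)

  # possible heterozygote counts share the parity of the rare count
  h_obs <- n_Aa
  hs <- seq(rare %% 2, rare, by = 2)
  probs <- numeric(length(hs))
  # start from the mid heterozygote count and apply the recurrence
  # P(h+2)/P(h) = 4 * n_rr(h) * n_cc(h) / ((h+2) * (h+1))
  # where n_rr, n_cc are the homozygote counts implied by h
  mid <- hs[which.min(abs(hs - rare * (2 * n - rare) / (2 * n)))]
  i_mid <- match(mid, hs)
  probs[i_mid] <- 1
  if (i_mid < length(hs)) {
    for (i in i_mid:(length(hs) - 1)) {
      h <- hs[i]
      n_rr <- (rare - h) / 2
      probs[i + 1] <- probs[i] * 4 * n_rr * (n - h - n_rr) /
        ((h + 2) * (h + 1))
    }
  }
  if (i_mid > 1) {
    for (i in i_mid:2) {
      h <- hs[i]
      n_rr <- (rare - h) / 2
      probs[i - 1] <- probs[i] * h * (h - 1) /
        (4 * (n_rr + 1) * (n - h - n_rr + 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(h_obs, hs)]
  if (is.na(p_obs)) stop("observed heterozygote count incompatible with allele counts")
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

# genotype counts from a dosage vector, NA if dosages are not integral
dosage_genotype_counts <- function(z) {
  z <- z[!is.na(z)]
  if (!length(z) || any(abs(z - round(z)) > 1e-6)) return(NULL)
  z <- round(z)
  c(n_AA = sum(z == 0), n_Aa = sum(z == 1), n_aa = sum(z == 2))
}

#' Filter variants on call rate, MAF and Hardy-Weinberg equilibrium
#'
#' Standard pre-association quality control.  A variant is kept only if
#' its per-variant call rate is at least `call_rate_min`, its minor
#' allele frequency (computed on non-missing calls) is at least
#' `maf_min`, and its exact HWE test p-value exceeds `hwe_p_min`.  The
#' HWE test needs genotype counts, so it is applied only to variants
#' whose non-missing dosages are (numerically) integers; imputed
#' fractional dosages skip that filter.
#'
#' @param gm A [genotype_matrix()].
#' @param call_rate_min,maf_min,hwe_p_min thresholds in `[0, 1]`;
#'   defaults 0.95, 0.05 and 1e-5.
#' @return A list with `genotypes` (the filtered [genotype_matrix()],
#'   possibly with zero variants) and `report` (data.frame `variant`,
#'   `reason` in `call_rate`/`maf`/`hwe`, `statistic`), one row per
#'   failed check, so a variant can appear more than once.
#' @export
qc_filter_variants <- function(gm, call_rate_min = 0.95, maf_min = 0.05,
                               hwe_p_min = 1e-5) {
  stopifnot(inherits(gm, "genotype_matrix"),
            call_rate_min >= 0, call_rate_min <= 1,
            maf_min >= 0, maf_min <= 1,
            hwe_p_min >= 0, hwe_p_min <= 1)
  d <- gm$dosage
  nv <- nrow(d)
  keep <- rep(TRUE, nv)
  rep_var <- character(0); rep_why <- character(0); rep_stat <- numeric(0)
  add <- function(v, why, stat) {
    rep_var <<- c(rep_var, v); rep_why <<- c(rep_why, why)
    rep_stat <<- c(rep_stat, stat)
  }
  for (i in seq_len(nv)) {
    v <- rownames(d)[i]
    z <- d[i, ]
    cr <- mean(!is.na(z))
    if (cr < call_rate_min) { keep[i] <- FALSE; add(v, "call_rate", cr) }
    zz <- z[!is.na(z)]
    af <- if (length(zz)) mean(zz) / 2 else NA_real_
    maf <- if (is.na(af)) NA_real_ else min(af, 1 - af)
    if (is.na(maf) || maf < maf_min) {
      keep[i] <- FALSE; add(v, "maf", maf)
    }
    cnt <- dosage_genotype_counts(z)
    if (!is.null(cnt) && sum(cnt) > 0) {
      p <- hwe_exact_pvalue(cnt[1], cnt[2], cnt[3])
      if (p <= hwe_p_min) { keep[i] <- FALSE; add(v, "hwe", p) }
    }
  }
  filtered <- genotype_matrix(d[keep, , drop = FALSE],
                              gm$effect_allele[keep])
  list(genotypes = filtered,
       report = data.frame(variant = rep_var, reason = rep_why,
                           statistic = rep_stat,
                           stringsAsFactors = FALSE))
}

#' Bonferroni significance threshold
#'
#' @param nominal_level family-wise error rate, default 0.05.
#' @param n_tests number of variants tested.
#' @return Per-test threshold `nominal_level / n_tests`.
#' @export
bonferroni_threshold <- function(nominal_level = 0.05, n_tests) {
  stopifnot(n_tests >= 1)
  nominal_level / n_tests
}
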