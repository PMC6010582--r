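# Per-SNP scan: QC integration, degenerate variants, two-stage identity.

make_scan_fixture <- function(n = 400, n_null = 3, seed = 314) {
  sim <- cached_sim(n, seed, 0.1)
  ids <- sim$cohort$survival$id
  set.seed(seed + 1)
  d <- rbind(causal = sim$truth$z,
             matrix(rbinom(n_null * n, 2, 0.3), n_null, n,
                    dimnames = list(paste0("null", seq_len(n_null)), NULL)))
  colnames(d) <- ids
  list(sim = sim, gm = genotype_matrix(d))
}

test_that("scan runs per variant, applies QC and flags degenerate variants", {
  fx <- make_scan_fixture()
  ids <- colnames(fx$gm$dosage)
  d <- rbind(fx$gm$dosage,
             mono = rep(0, length(ids)),
             rare = rbinom(length(ids), 2, 0.01))
  colnames(d) <- ids
  gm <- genotype_matrix(d)
  res <- scan_variants(fx$sim$cohort, gm, method = "TS")
  # monomorphic and rare variants are both removed by default QC (MAF)
  expect_false("rare" %in% res$variant)
  expect_false("mono" %in% res$variant)
  done <- res[res$note == "", ]
  expect_true(all(done$gamma_p > 0 & done$gamma_p <= 1))
  # Bonferroni threshold counts the variants actually tested
  expect_equal(attr(res, "bonferroni"), 0.05 / nrow(res))
  # without QC the monomorphic variant is flagged, not fitted
  res2 <- scan_variants(fx$sim$cohort, gm, method = "TS", qc = FALSE)
  expect_match(res2$note[res2$variant == "mono"], "no variation")
  expect_true(is.na(res2$gamma[res2$variant == "mono"]))
})

test_that("scan results do not depend on variant order", {
  fx <- make_scan_fixture(n = 300, n_null = 2, seed = 3140)
  res1 <- scan_variants(fx$sim$cohort, fx$gm, method = "TS", qc = FALSE)
  perm <- c(2, 3, 1)
  gm2 <- genotype_matrix(fx$gm$dosage[perm, , drop = FALSE],
                         fx$gm$effect_allele[perm])
  res2 <- scan_variants(fx$sim$cohort, gm2, method = "TS", qc = FALSE)
  res2 <- res2[match(res1$variant, res2$variant), ]
  rownames(res2) <- NULL
  expect_equal(res1, res2, ignore_attr = TRUE)
})

test_that("two-stage scan refits exactly the pre-filter survivors with JM", {
  fx <- make_scan_fixture(n = 250, n_null = 2, seed = 9000)
  quad <- quadrature_spec(5)
  full_jm <- scan_variants(fx$sim$cohort, fx$gm, method = "JM", qc = FALSE,
                           quad = quad)
  two <- two_stage_scan(fx$sim$cohort, fx$gm, prefilter_p = 0.5,
                        qc = FALSE, quad = quad)
  jm_rows <- two[two$method == "JM", ]
  expect_true(all(jm_rows$variant %in% full_jm$variant))
  expect_gte(nrow(jm_rows), 1)
  for (v in jm_rows$variant) {
    a <- jm_rows[jm_rows$variant == v, ]
    b <- full_jm[full_jm$variant == v, ]
    rownames(a) <- rownames(b) <- NULL
    expect_equal(a, b, ignore_attr = TRUE)
  }
  # prefilter at 1 degenerates to a full JM scan; near 0 refits nothing
  two_all <- two_stage_scan(fx$sim$cohort, fx$gm, prefilter_p = 1,
                            qc = FALSE, quad = quad)
  expect_equal(sum(two_all$method == "JM"), nrow(fx$gm$dosage))
  two_none <- two_stage_scan(fx$sim$cohort, fx$gm, prefilter_p = 1e-12,
                             qc = FALSE, quad = quad)
  expect_equal(sum(two_none$method == "JM"), 0)
})

test_that("a scan with zero surviving variants errors", {
  fx <- make_scan_fixture(n = 200, n_null = 1, seed = 11000)
  ids <- colnames(fx$gm$dosage)
  gm <- genotype_matrix(matrix(rbinom(length(ids), 2, 0.005), 1,
                               dimnames = list("rare", ids)))
  expect_error(scan_variants(fx$sim$cohort, gm), "zero variants")
})
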