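# Cohort container, delimited readers/writers, genotype formats.

test_that("cohort round trip through delimited files preserves every field", {
  co <- tiny_cohort()
  lp <- tempfile(fileext = ".tsv"); sp <- tempfile(fileext = ".csv")
  write_cohort(co, lp, sp)
  co2 <- read_cohort(lp, sp)
  expect_identical(co2$longitudinal, co$longitudinal)
  expect_identical(co2$survival, co$survival)
  unlink(c(lp, sp))
})

test_that("validation rejects measurements after the observed time, with the record listed", {
  long <- data.frame(id = c("x", "x"), time = c(0, 8), value = c(5, 5.2))
  surv <- data.frame(id = "x", time = 6, status = 1)
  expect_error(cohort_data(long, surv), "t=8.*observed time 6")
})

test_that("degenerate and malformed inputs fail with clear messages", {
  long <- data.frame(id = "x", time = 0, value = 5)
  expect_error(cohort_data(long, data.frame(id = character(0),
                                            time = numeric(0),
                                            status = numeric(0))),
               "no survival records")
  sp <- tempfile(fileext = ".tsv")
  writeLines("id\ttime\tstatus", sp)
  lp <- tempfile(fileext = ".tsv")
  utils::write.table(long, lp, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_cohort(lp, sp), "no survival records")
  unlink(c(lp, sp))
  # missing column
  expect_error(cohort_data(data.frame(id = "x", time = 0),
                           data.frame(id = "x", time = 1, status = 1)),
               "missing column")
  # id mismatch
  expect_error(cohort_data(long, data.frame(id = "y", time = 1, status = 1)),
               "id mismatch")
  # non-increasing times
  expect_error(cohort_data(data.frame(id = c("x", "x"), time = c(3, 3),
                                      value = c(5, 5)),
                           data.frame(id = "x", time = 6, status = 0)),
               "strictly increasing")
})

test_that("VCF genotypes are coded additively on the ALT allele", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0|1\t./.\t1|1"),
    vcf)
  gm <- read_genotypes(vcf, "vcf")
  expect_equal(unname(gm$dosage["rs1", ]), c(0, 1, 2))
  expect_equal(unname(gm$dosage["rs2", ]), c(1, NA, 2))
  expect_equal(gm$effect_allele, c("G", "T"))
  unlink(vcf)
})

test_that("dosage tables round trip and reject out-of-range dosages", {
  d <- matrix(c(0, 1.5, 2, NA, 0.25, 1), 2, 3,
              dimnames = list(c("v1", "v2"), c("a", "b", "c")))
  gm <- genotype_matrix(d, c("A", "C"))
  path <- tempfile(fileext = ".tsv")
  write_genotypes(gm, path)
  gm2 <- read_genotypes(path, "dosage_table")
  expect_identical(gm2$dosage, gm$dosage)
  expect_identical(gm2$effect_allele, gm$effect_allele)
  unlink(path)
  expect_error(genotype_matrix(matrix(2.5, 1, 1,
                                      dimnames = list("v", "a"))),
               "dosage outside")
})
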