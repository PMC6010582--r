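# Readers and writers for the delimited formats the package touches:
# cohort tables (CSV/TSV), dosage tables (TSV) and VCF.

read_table_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = c("NA", ""))
}

#' Read a cohort from delimited files
#'
#' @param longitudinal_path CSV/TSV with header columns `id`, `time`
#'   (years), `value`.
#' @param survival_path CSV/TSV with header columns `id`, `time` (years),
#'   `status` (0/1).
#' @param covariate_path optional CSV/TSV with header column `id` plus
#'   numeric covariates.
#' @return A validated [cohort_data()] object.  Records violating the
#'   dropout invariant (a measurement after the observed survival time)
#'   cause an error that lists the offending records.
#' @export
read_cohort <- function(longitudinal_path, survival_path,
                        covariate_path = NULL) {
  long <- read_table_auto(longitudinal_path)
  surv <- read_table_auto(survival_path)
  if (nrow(surv) == 0L) stop("no survival records", call. = FALSE)
  cov <- if (!is.null(covariate_path)) read_table_auto(covariate_path)
  cohort_data(long, surv, covariates = cov)
}

#' Write a cohort to delimited files
#'
#' Inverse of [read_cohort()]; the round trip preserves every field.
#'
#' @param cohort A [cohort_data()] object.
#' @param longitudinal_path,survival_path,covariate_path output paths;
#'   extension `.csv` selects comma separation, anything else tab.
#'   `covariate_path` is ignored when the cohort has no covariates.
#' @return Invisibly, the cohort.
#' @export
write_cohort <- function(cohort, longitudinal_path, survival_path,
                         covariate_path = NULL) {
  wr <- function(df, path) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  }
  wr(cohort$longitudinal, longitudinal_path)
  wr(cohort$survival, survival_path)
  if (!is.null(cohort$covariates) && !is.null(covariate_path)) {
    wr(cohort$covariates, covariate_path)
  }
  invisible(cohort)
}

#' Read genotypes from VCF or a plain dosage table
#'
#' VCF input uses the `DS` FORMAT field when present, otherwise additive
#' coding of `GT` (count of ALT alleles; half-calls and missing genotypes
#' become `NA`).  The dosage-table format is tab-delimited with variants
#' in rows: a `variant` column, an optional `effect_allele` column, then
#' one column per individual; empty cells or `NA` mark missing calls.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"vcf"` or `"dosage_table"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage_table")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
      "vcf"
    } else {
      "dosage_table"
    }
  }
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_dosage(path)
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ids <- ifelse(is.na(v@fix[, "ID"]) | v@fix[, "ID"] == ".",
                paste0(v@fix[, "CHROM"], ":", v@fix[, "POS"]),
                v@fix[, "ID"])
  fmt <- v@gt[, 1]
  has_ds <- all(vapply(strsplit(fmt, ":"), function(f) "DS" %in% f, logical(1)))
  if (has_ds) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    count_alt <- function(g) {
      if (is.na(g)) return(NA_real_)
      al <- strsplit(g, "[/|]")[[1]]
      if (any(al == ".")) return(NA_real_)
      sum(al != "0")
    }
    ds <- matrix(vapply(gt, count_alt, numeric(1)), nrow = nrow(gt),
                 dimnames = dimnames(gt))
  }
  rownames(ds) <- ids
  genotype_matrix(ds, effect_allele = v@fix[, "ALT"])
}

read_genotypes_dosage <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  if (!"variant" %in% names(df)) {
    stop("dosage table must have a 'variant' column")
  }
  ea <- if ("effect_allele" %in% names(df)) df$effect_allele
  keep <- setdiff(names(df), c("variant", "effect_allele"))
  if (!length(keep)) stop("dosage table has no individual columns")
  m <- as.matrix(df[keep])
  storage.mode(m) <- "double"
  rownames(m) <- df$variant
  genotype_matrix(m, effect_allele = ea)
}

#' Write a genotype matrix as a dosage table
#'
#' @param gm A [genotype_matrix()].
#' @param path output TSV path.
#' @return Invisibly, `gm`.
#' @export
write_genotypes <- function(gm, path) {
  df <- data.frame(variant = rownames(gm$dosage),
                   effect_allele = gm$effect_allele,
                   gm$dosage, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(gm)
}
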