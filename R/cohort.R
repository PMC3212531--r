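#' Construct a genotype matrix
#'
#' The central genotype container: an `n_samples x n_snps` grid of
#' minor-allele dosages (0, 1, 2 or `NA` for missing) together with SNP
#' metadata. Dosages always count copies of the *minor* allele, where the
#' minor allele is defined on the pooled (cases + controls) sample.
#'
#' @param dosages integer matrix, samples in rows, SNPs in columns; values
#'   in `{0, 1, 2, NA}`.
#' @param snps data frame with columns `snp_id`, `chrom`, `bp`,
#'   `allele_minor`, `allele_major` and optionally `risk_allele`
#'   (`"minor"`, `"major"` or `"unset"`).
#' @param samples character vector of sample ids, one per row of `dosages`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `snps`, `samples`.
#' @examples
#' gm <- genotype_matrix(
#'   dosages = rbind(c(0, 1), c(1, 2), c(2, 0)),
#'   snps = data.frame(snp_id = c("s1", "s2"), chrom = "6",
#'                     bp = c(100L, 200L),
#'                     allele_minor = c("G", "T"), allele_major = c("A", "C")),
#'   samples = c("id1", "id2", "id3"))
#' dim(gm$dosages)
#' @export
genotype_matrix <- function(dosages, snps, samples) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (is.null(snps$risk_allele)) snps$risk_allele <- "unset"
  snps$snp_id <- as.character(snps$snp_id)
  snps$chrom <- as.character(snps$chrom)
  snps$bp <- as.integer(snps$bp)
  obj <- structure(list(dosages = dosages,
                        snps = as.data.frame(snps, stringsAsFactors = FALSE),
                        samples = as.character(samples)),
                   class = "genotype_matrix")
  validate_genotype_matrix(obj)
  obj
}

validate_genotype_matrix <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (nrow(x$dosages) != length(x$samples))
    stop("dosage rows (", nrow(x$dosages), ") != number of samples (",
         length(x$samples), ")", call. = FALSE)
  if (ncol(x$dosages) != nrow(x$snps))
    stop("dosage columns (", ncol(x$dosages), ") != number of SNPs (",
         nrow(x$snps), ")", call. = FALSE)
  need <- c("snp_id", "chrom", "bp", "allele_minor", "allele_major",
            "risk_allele")
  miss <- setdiff(need, names(x$snps))
  if (length(miss)) stop("snps table lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(x$snps$snp_id))
    stop("duplicated snp_id in cohort", call. = FALSE)
  if (any(x$snps$bp <= 0, na.rm = TRUE)) stop("bp must be > 0", call. = FALSE)
  bad <- x$snps$allele_minor == x$snps$allele_major &
    !is.na(x$snps$allele_minor)
  if (any(bad)) stop("allele_minor == allele_major for: ",
                     paste(x$snps$snp_id[bad], collapse = ", "),
                     call. = FALSE)
  v <- x$dosages[!is.na(x$dosages)]
  if (length(v) && (min(v) < 0L || max(v) > 2L))
    stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  invisible(x)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", length(x$samples), " samples x ",
      nrow(x$snps), " SNPs\n", sep = "")
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing rate: %.4f\n", miss))
  invisible(x)
}

snp_index <- function(geno, snp_id) {
  i <- match(snp_id, geno$snps$snp_id)
  if (anyNA(i)) stop("SNP not found in cohort: ",
                     paste(snp_id[is.na(i)], collapse = ", "), call. = FALSE)
  i
}

#' Extract the dosage vector of one SNP
#' @param geno a [genotype_matrix()].
#' @param snp_id single SNP id.
#' @return integer vector of minor-allele dosages, named by sample id.
#' @export
snp_dosage <- function(geno, snp_id) {
  d <- geno$dosages[, snp_index(geno, snp_id)]
  names(d) <- geno$samples
  d
}

#' Validate a covariate table
#'
#' A covariate table is a plain data frame with one row per sample and
#' columns `sample_id`, `status` (1 = case, 0 = control), `age`, `sex`,
#' `pc1`, `pc2` and `study`. `status` must be non-missing.
#'
#' @param x data frame to validate.
#' @return `x`, invisibly, after checks.
#' @export
validate_covariate_table <- function(x) {
  need <- c("sample_id", "status", "age", "sex", "pc1", "pc2", "study")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("covariate table lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyNA(x$status)) stop("status must be non-missing", call. = FALSE)
  if (!all(x$status %in% c(0, 1)))
    stop("status must be 0 (control) or 1 (case)", call. = FALSE)
  if (anyDuplicated(x$sample_id))
    stop("duplicated sample_id in covariate table", call. = FALSE)
  invisible(x)
}

#' Align covariates to the genotype sample order
#'
#' Samples present in the genotype matrix but absent from the covariate
#' table are kept in the cohort but flagged; they are dropped from any
#' fitted model (complete-case analysis).
#'
#' @param geno a [genotype_matrix()].
#' @param covar a covariate table.
#' @return data frame with rows in `geno$samples` order; rows for samples
#'   without covariates are filled with `NA` (and `status` `NA`), with the
#'   affected ids in `attr(, "samples_without_covariates")`.
#' @export
align_covariates <- function(geno, covar) {
  validate_covariate_table(covar)
  i <- match(geno$samples, covar$sample_id)
  out <- covar[i, , drop = FALSE]
  out$sample_id <- geno$samples
  rownames(out) <- NULL
  attr(out, "samples_without_covariates") <- geno$samples[is.na(i)]
  out
}

#' Per-SNP summary statistics
#'
#' Minor allele frequency in cases and controls, missingness and an exact
#' Hardy-Weinberg equilibrium P value. Dosages are minor-allele oriented on
#' the pooled sample, so a *stratum* frequency may exceed 0.5; when that
#' happens the row is flagged rather than silently re-oriented per stratum.
#'
#' @param geno a [genotype_matrix()].
#' @param covar covariate table (used for case/control status).
#' @param snp_id SNP to summarise.
#' @param hwe_stratum stratum on which the exact HWE test is computed;
#'   `"controls"` (default, standard GWAS-QC practice) or `"all"`.
#' @return list with `snp_id`, `maf_cases`, `maf_controls`, `missing_rate`,
#'   `hwe_p` and logical `stratum_flip_flag`.
#' @export
snp_summary <- function(geno, covar, snp_id,
                        hwe_stratum = c("controls", "all")) {
  hwe_stratum <- match.arg(hwe_stratum)
  dos <- snp_dosage(geno, snp_id)
  if (all(is.na(dos)))
    stop("all genotypes missing for ", snp_id, "; summary undefined",
         call. = FALSE)
  cv <- align_covariates(geno, covar)
  status <- cv$status
  maf_of <- function(d) if (sum(!is.na(d)) == 0) NA_real_ else
    mean(d, na.rm = TRUE) / 2
  maf_cases <- maf_of(dos[!is.na(status) & status == 1])
  maf_controls <- maf_of(dos[!is.na(status) & status == 0])
  hd <- if (hwe_stratum == "controls")
    dos[!is.na(status) & status == 0] else dos
  hd <- hd[!is.na(hd)]
  hwe_p <- if (length(hd) == 0) NA_real_ else
    hwe_exact_p(sum(hd == 2L), sum(hd == 1L), sum(hd == 0L))
  list(snp_id = snp_id,
       maf_cases = maf_cases,
       maf_controls = maf_controls,
       missing_rate = mean(is.na(dos)),
       hwe_p = hwe_p,
       stratum_flip_flag = isTRUE(maf_cases > 0.5) ||
         isTRUE(maf_controls > 0.5))
}
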