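#' Read a case-control cohort from PLINK PED/MAP text files
#'
#' Whitespace-delimited PED (6 leading columns: family id, sample id,
#' paternal id, maternal id, sex, phenotype) followed by two allele columns
#' per SNP; `0` is the missing-allele code. The MAP file carries `chrom`,
#' `snp_id`, `cM`, `bp`. Dosages are coded as counts of the minor allele,
#' where minor/major are determined from the pooled sample (ties broken by
#' alphabetical order, the earlier letter taken as minor). Samples absent
#' from the covariate table are retained but flagged for exclusion from
#' fitted models.
#'
#' @param ped_path,map_path PED and MAP file paths.
#' @param covariate_path tab-separated covariate file with header
#'   `sample_id status age sex pc1 pc2 study`.
#' @return list with elements `genotypes` (a [genotype_matrix()]) and
#'   `covariates` (covariate table aligned to the genotype sample order).
#' @export
read_cohort <- function(ped_path, map_path, covariate_path) {
  for (p in c(ped_path, map_path, covariate_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  map <- utils::read.table(map_path, header = FALSE,
                           colClasses = c("character", "character",
                                          "numeric", "integer"))
  names(map) <- c("chrom", "snp_id", "cm", "bp")
  m <- nrow(map)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  samples <- character(n)
  pheno <- integer(n)
  a1 <- matrix("0", n, m)
  a2 <- matrix("0", n, m)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6 + 2 * m)
      stop("malformed PED line ", i, ": expected ", 6 + 2 * m,
           " fields, found ", length(f), call. = FALSE)
    samples[i] <- f[2]
    pheno[i] <- suppressWarnings(as.integer(f[6]))
    a1[i, ] <- f[seq(7, by = 2, length.out = m)]
    a2[i, ] <- f[seq(8, by = 2, length.out = m)]
  }

  dosages <- matrix(NA_integer_, n, m)
  allele_minor <- character(m)
  allele_major <- character(m)
  for (j in seq_len(m)) {
    al <- c(a1[, j], a2[, j])
    obs <- al[al != "0"]
    tab <- sort(table(obs))
    if (length(tab) > 2)
      stop("SNP ", map$snp_id[j], " has >2 observed alleles: ",
           paste(names(tab), collapse = ","), call. = FALSE)
    if (length(tab) == 0) {       # fully missing SNP
      allele_minor[j] <- "N"; allele_major[j] <- "0"
      next
    }
    if (length(tab) == 1) {       # monomorphic: minor allele letter unknown
      allele_major[j] <- names(tab)
      allele_minor[j] <- "N"
      minor <- "N"
    } else {
      # rarer allele is minor; at a tie the alphabetically earlier letter
      if (tab[[1]] == tab[[2]]) {
        nm <- sort(names(tab))
        allele_minor[j] <- nm[1]; allele_major[j] <- nm[2]
      } else {
        allele_minor[j] <- names(tab)[1]; allele_major[j] <- names(tab)[2]
      }
      minor <- allele_minor[j]
    }
    missing <- a1[, j] == "0" | a2[, j] == "0"
    d <- (a1[, j] == minor) + (a2[, j] == minor)
    d[missing] <- NA_integer_
    dosages[, j] <- d
  }

  geno <- genotype_matrix(
    dosages,
    data.frame(snp_id = map$snp_id, chrom = map$chrom, bp = map$bp,
               allele_minor = allele_minor, allele_major = allele_major,
               stringsAsFactors = FALSE),
    samples)

  covar <- utils::read.table(covariate_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  covar$sample_id <- as.character(covar$sample_id)
  covar <- align_covariates(geno, covar)
  list(genotypes = geno, covariates = covar)
}

#' Write a cohort as PED/MAP plus a covariate TSV
#'
#' Inverse of [read_cohort()]: missing genotypes become `0 0`, the PED
#' phenotype column carries 2 for cases and 1 for controls (-9 when status
#' is unknown).
#'
#' @param geno a [genotype_matrix()].
#' @param covar covariate table (may omit samples; they get phenotype -9).
#' @param out_prefix path prefix; writes `<prefix>.ped`, `<prefix>.map`,
#'   `<prefix>.cov.tsv`.
#' @return the three file paths, invisibly.
#' @export
write_cohort <- function(geno, covar, out_prefix) {
  validate_genotype_matrix(geno)
  cv <- if (nrow(covar) || length(geno$samples) == 0)
    tryCatch(align_covariates(geno, covar), error = function(e) covar)
  else covar
  ped_path <- paste0(out_prefix, ".ped")
  map_path <- paste0(out_prefix, ".map")
  cov_path <- paste0(out_prefix, ".cov.tsv")

  map <- data.frame(chrom = geno$snps$chrom, snp_id = geno$snps$snp_id,
                    cm = 0, bp = geno$snps$bp)
  utils::write.table(map, map_path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)

  n <- length(geno$samples)
  m <- nrow(geno$snps)
  status <- if (n && nrow(cv)) cv$status[match(geno$samples, cv$sample_id)]
  else rep(NA_integer_, n)
  pheno <- ifelse(is.na(status), -9L, status + 1L)
  sex <- if (n && nrow(cv)) cv$sex[match(geno$samples, cv$sample_id)]
  else rep(NA_integer_, n)
  sexcol <- ifelse(is.na(sex), 0L, as.integer(sex) + 1L)

  con <- file(ped_path, "w")
  on.exit(close(con))
  for (i in seq_len(n)) {
    g <- character(2 * m)
    for (j in seq_len(m)) {
      d <- geno$dosages[i, j]
      pair <- if (is.na(d)) c("0", "0")
      else if (d == 0L) rep(geno$snps$allele_major[j], 2)
      else if (d == 1L) c(geno$snps$allele_minor[j],
                          geno$snps$allele_major[j])
      else rep(geno$snps$allele_minor[j], 2)
      g[c(2 * j - 1, 2 * j)] <- pair
    }
    writeLines(paste(c("FAM", geno$samples[i], "0", "0", sexcol[i],
                       pheno[i], g), collapse = " "), con)
  }

  cols <- c("sample_id", "status", "age", "sex", "pc1", "pc2", "study")
  cv_out <- if (nrow(cv)) cv[, cols, drop = FALSE]
  else stats::setNames(as.data.frame(matrix(nrow = 0, ncol = 7)), cols)
  utils::write.table(cv_out, cov_path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(c(ped = ped_path, map = map_path, cov = cov_path))
}

#' Minimal VCF v4.2 reader (GT field only, biallelic records)
#'
#' Reads an uncompressed VCF, keeps biallelic SNP records, takes the GT
#' subfield, and returns a pooled minor-allele oriented [genotype_matrix()].
#' Phasing separators (`|` or `/`) are ignored; any genotype containing `.`
#' is treated as missing.
#'
#' @param path VCF file path.
#' @return a [genotype_matrix()].
#' @export
read_vcf_minimal <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("no #CHROM header line", call. = FALSE)
  hf <- strsplit(lines[hdr[1]], "\t")[[1]]
  samples <- hf[-(1:9)]
  body <- lines[-seq_len(hdr[1])]
  body <- body[nzchar(body)]
  ids <- chrs <- ref <- alt <- character(0)
  bps <- integer(0)
  dos <- list()
  for (k in seq_along(body)) {
    f <- strsplit(body[k], "\t")[[1]]
    if (length(f) != length(hf))
      stop("malformed VCF record at data line ", k, call. = FALSE)
    if (grepl(",", f[5])) next  # multi-allelic: skip
    gtpos <- match("GT", strsplit(f[9], ":")[[1]])
    if (is.na(gtpos)) stop("record without GT at data line ", k,
                           call. = FALSE)
    gts <- vapply(strsplit(f[-(1:9)], ":"), `[`, "", gtpos)
    alleles <- strsplit(gts, "[|/]")
    d <- vapply(alleles, function(a) {
      if (any(a == ".")) NA_integer_ else sum(a == "1")
    }, NA_integer_)
    ids <- c(ids, if (f[3] == ".") paste0(f[1], ":", f[2]) else f[3])
    chrs <- c(chrs, f[1]); bps <- c(bps, as.integer(f[2]))
    ref <- c(ref, f[4]); alt <- c(alt, f[5])
    dos[[length(dos) + 1L]] <- d
  }
  m <- length(dos)
  dmat <- if (m) do.call(cbind, dos) else
    matrix(NA_integer_, length(samples), 0)
  # orient to pooled minor allele
  allele_minor <- alt; allele_major <- ref
  for (j in seq_len(m)) {
    f1 <- mean(dmat[, j], na.rm = TRUE) / 2
    if (!is.nan(f1) && f1 > 0.5) {
      dmat[, j] <- 2L - dmat[, j]
      allele_minor[j] <- ref[j]; allele_major[j] <- alt[j]
    }
  }
  genotype_matrix(dmat,
                  data.frame(snp_id = ids, chrom = chrs, bp = bps,
                             allele_minor = allele_minor,
                             allele_major = allele_major,
                             stringsAsFactors = FALSE),
                  samples)
}
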