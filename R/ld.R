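#' Two-locus haplotype frequencies by EM from unphased genotypes
#'
#' Estimates the four haplotype frequencies (minor-minor, minor-major,
#' major-minor, major-major) for a pair of biallelic SNPs from dosage data.
#' Only double heterozygotes are phase-ambiguous; all other genotype
#' classes contribute fixed haplotype counts. The EM starts at linkage
#' equilibrium (product of allele frequencies) and stops when the largest
#' absolute frequency change is below `tol` (default `1e-8`) or after
#' `max_iter` iterations. The observed-data log-likelihood is
#' non-decreasing across iterations and is returned for inspection.
#'
#' @param dos_a,dos_b dosage vectors (0/1/2/NA) for the two SNPs; samples
#'   missing either genotype are excluded pairwise.
#' @param tol,max_iter convergence controls.
#' @return list with `freqs` (named `mm`, `mM`, `Mm`, `MM`: first letter =
#'   allele at SNP a, second = SNP b, `m` = minor copy), `loglik` (trace),
#'   `iterations`, `converged`, `n`.
#' @export
two_locus_em <- function(dos_a, dos_b, tol = 1e-8, max_iter = 1000) {
  keep <- !is.na(dos_a) & !is.na(dos_b)
  a <- dos_a[keep]; b <- dos_b[keep]
  n <- length(a)
  if (n < 1) stop("no samples with both genotypes observed", call. = FALSE)
  # 3x3 genotype table, rows = dosage at a (0,1,2), cols = dosage at b
  tab <- matrix(0, 3, 3)
  for (i in 0:2) for (j in 0:2) tab[i + 1, j + 1] <- sum(a == i & b == j)

  pa <- mean(a) / 2; pb <- mean(b) / 2
  # fixed haplotype counts from the eight unambiguous cells
  # haplotypes: 1 = mm, 2 = mM, 3 = Mm, 4 = MM (m = minor allele copy)
  fixed <- numeric(4)
  add <- function(h, k) fixed[h] <<- fixed[h] + k
  add(4, 2 * tab[1, 1]); add(3, tab[1, 2]); add(4, tab[1, 2])
  add(3, 2 * tab[1, 3])
  add(2, tab[2, 1]); add(4, tab[2, 1])
  add(1, tab[2, 3]); add(3, tab[2, 3])
  add(2, 2 * tab[3, 1]); add(1, tab[3, 2]); add(2, tab[3, 2])
  add(1, 2 * tab[3, 3])
  ndh <- tab[2, 2]  # double heterozygotes: mm/MM vs mM/Mm

  f <- c(pa * pb, pa * (1 - pb), (1 - pa) * pb, (1 - pa) * (1 - pb))
  f <- pmax(f, 1e-12); f <- f / sum(f)
  ll <- function(f) {
    lf <- log(pmax(f, 1e-300))
    s <- fixed[1] * lf[1] + fixed[2] * lf[2] + fixed[3] * lf[3] +
      fixed[4] * lf[4]
    # unambiguous double counts above already use per-haplotype factors;
    # the double-het cell likelihood is 2(f1 f4 + f2 f3)
    if (ndh > 0) s <- s + ndh * log(pmax(2 * (f[1] * f[4] + f[2] * f[3]),
                                         1e-300))
    s
  }
  trace <- ll(f)
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    denom <- f[1] * f[4] + f[2] * f[3]
    w_cis <- if (denom > 0) f[1] * f[4] / denom else 0.5
    cnt <- fixed
    cnt[c(1, 4)] <- cnt[c(1, 4)] + ndh * w_cis
    cnt[c(2, 3)] <- cnt[c(2, 3)] + ndh * (1 - w_cis)
    f_new <- cnt / (2 * n)
    trace <- c(trace, ll(f_new))
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) {converged <- TRUE; break}
  }
  list(freqs = stats::setNames(f, c("mm", "mM", "Mm", "MM")),
       loglik = trace, iterations = it, converged = converged, n = n)
}

#' Pairwise linkage disequilibrium (D, D', r2)
#'
#' Haplotype frequencies come from [two_locus_em()] on the cohort's
#' unphased dosages; D is the haplotype-frequency covariance of the two
#' minor-allele indicators, D' scales |D| by its maximum attainable
#' magnitude given the allele frequencies, and r2 is the squared allelic
#' correlation. `d = 0` gives `d_prime = 0` by convention; a monomorphic
#' SNP gives a degenerate result flagged `undefined`.
#'
#' @param geno a [genotype_matrix()].
#' @param snp_a,snp_b SNP ids (identical ids give D' = r2 = 1).
#' @return list with `snp_a`, `snp_b`, `p_a`, `p_b` (minor-allele
#'   frequencies), `p_ab`, `d`, `d_prime`, `r2`, `n`, `undefined`.
#' @export
ld_pair <- function(geno, snp_a, snp_b) {
  if (identical(snp_a, snp_b)) {
    p <- mean(snp_dosage(geno, snp_a), na.rm = TRUE) / 2
    return(list(snp_a = snp_a, snp_b = snp_b, p_a = p, p_b = p,
                p_ab = p, d = p * (1 - p), d_prime = 1, r2 = 1,
                n = sum(!is.na(snp_dosage(geno, snp_a))),
                undefined = p %in% c(0, 1)))
  }
  em <- two_locus_em(snp_dosage(geno, snp_a), snp_dosage(geno, snp_b))
  f <- em$freqs
  p_a <- f[["mm"]] + f[["mM"]]
  p_b <- f[["mm"]] + f[["Mm"]]
  p_ab <- f[["mm"]]
  d <- p_ab - p_a * p_b
  if (p_a %in% c(0, 1) || p_b %in% c(0, 1)) {
    return(list(snp_a = snp_a, snp_b = snp_b, p_a = p_a, p_b = p_b,
                p_ab = p_ab, d = 0, d_prime = 0, r2 = 0, n = em$n,
                undefined = TRUE))
  }
  d_max <- if (d > 0) min(p_a * (1 - p_b), (1 - p_a) * p_b)
  else if (d < 0) min(p_a * p_b, (1 - p_a) * (1 - p_b))
  else NA_real_
  d_prime <- if (d == 0) 0 else abs(d) / d_max
  r2 <- d^2 / (p_a * (1 - p_a) * p_b * (1 - p_b))
  list(snp_a = snp_a, snp_b = snp_b, p_a = p_a, p_b = p_b, p_ab = p_ab,
       d = d, d_prime = min(d_prime, 1), r2 = min(r2, 1), n = em$n,
       undefined = FALSE)
}

#' Pairwise LD matrices for a SNP set
#'
#' @param geno a [genotype_matrix()].
#' @param snp_ids at least two SNP ids.
#' @return list of two symmetric matrices, `d_prime` and `r2`, with unit
#'   diagonal and `NA` where a pair was undefined (monomorphic member).
#' @export
ld_matrix <- function(geno, snp_ids) {
  k <- length(snp_ids)
  if (k < 2) stop("need at least 2 SNPs", call. = FALSE)
  dp <- r2 <- matrix(NA_real_, k, k, dimnames = list(snp_ids, snp_ids))
  diag(dp) <- diag(r2) <- 1
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    p <- ld_pair(geno, snp_ids[i], snp_ids[j])
    if (!p$undefined) {
      dp[i, j] <- dp[j, i] <- p$d_prime
      r2[i, j] <- r2[j, i] <- p$r2
    }
  }
  list(d_prime = dp, r2 = r2)
}

#' Long-format pairwise LD table
#'
#' One row per unordered SNP pair with D, D' and r2 — the long-format
#' companion of [ld_matrix()].
#'
#' @param geno a [genotype_matrix()].
#' @param snp_ids at least two SNP ids.
#' @return data frame with columns `snp_a`, `snp_b`, `d`, `d_prime`, `r2`.
#' @export
ld_long <- function(geno, snp_ids) {
  k <- length(snp_ids)
  if (k < 2) stop("need at least 2 SNPs", call. = FALSE)
  rows <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    p <- ld_pair(geno, snp_ids[i], snp_ids[j])
    rows[[length(rows) + 1L]] <- data.frame(
      snp_a = p$snp_a, snp_b = p$snp_b,
      d = if (p$undefined) NA_real_ else p$d,
      d_prime = if (p$undefined) NA_real_ else p$d_prime,
      r2 = if (p$undefined) NA_real_ else p$r2)
  }
  do.call(rbind, rows)
}

#' Write an LD matrix as TSV (snp ids as header row and column)
#' @param mat square matrix from [ld_matrix()].
#' @param path output file.
#' @return path, invisibly.
#' @export
write_ld_tsv <- function(mat, path) {
  df <- data.frame(snp_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Read an LD matrix TSV written by [write_ld_tsv()]
#' @param path file path.
#' @return numeric matrix with snp ids as dimnames.
#' @export
read_ld_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$snp_id
  m
}
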