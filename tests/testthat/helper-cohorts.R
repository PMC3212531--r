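# Shared fixtures and independent oracles. Everything is generated in code;
# oracles deliberately avoid the code paths they check.

make_snps <- function(m, minor = NULL, major = NULL) {
  pairs <- list(c("G", "A"), c("T", "C"), c("C", "G"), c("A", "T"))
  al <- pairs[(seq_len(m) - 1) %% 4 + 1]
  data.frame(snp_id = sprintf("s%02d", seq_len(m)), chrom = "6",
             bp = as.integer(1000 * seq_len(m)),
             allele_minor = if (is.null(minor)) vapply(al, `[`, "", 1) else minor,
             allele_major = if (is.null(major)) vapply(al, `[`, "", 2) else major,
             risk_allele = "unset", stringsAsFactors = FALSE)
}

make_covar <- function(status, age = NULL, sex = NULL, pc1 = NULL,
                       pc2 = NULL, study = "A",
                       ids = sprintf("id%04d", seq_along(status))) {
  n <- length(status)
  data.frame(sample_id = ids, status = status,
             age = if (is.null(age)) rep(60, n) else age,
             sex = if (is.null(sex)) rep(0L, n) else sex,
             pc1 = if (is.null(pc1)) rep(0, n) else pc1,
             pc2 = if (is.null(pc2)) rep(0, n) else pc2,
             study = study, stringsAsFactors = FALSE)
}

# random small cohort: independent SNPs, random case/control labels
random_cohort <- function(n, m, seed, maf_range = c(0.1, 0.5)) {
  set.seed(seed)
  mafs <- runif(m, maf_range[1], maf_range[2])
  dos <- vapply(mafs, function(p) rbinom(n, 2, p), integer(n))
  geno <- genotype_matrix(dos, make_snps(m), sprintf("id%04d", seq_len(n)))
  covar <- make_covar(rbinom(n, 1, 0.5),
                      age = rnorm(n, 60, 8), sex = rbinom(n, 1, 0.5),
                      pc1 = rnorm(n), pc2 = rnorm(n))
  list(genotypes = geno, covariates = covar)
}

# ---- independent oracles -------------------------------------------------

# HWE enumeration oracle: direct log-factorial evaluation of the
# conditional distribution of heterozygote counts given allele counts
oracle_hwe_enum <- function(n_mm, n_het, n_MM) {
  n <- n_mm + n_het + n_MM
  nr <- 2 * n_mm + n_het
  if (nr > n) nr <- 2 * n - nr
  if (nr == 0) return(1)
  hs <- seq(nr %% 2, min(nr, 2 * n - nr), by = 2)
  lp <- vapply(hs, function(h) {
    lgamma(n + 1) - lgamma((nr - h) / 2 + 1) - lgamma(h + 1) -
      lgamma((2 * n - nr - h) / 2 + 1) + h * log(2) +
      lgamma(nr + 1) + lgamma(2 * n - nr + 1) - lgamma(2 * n + 1)
  }, 0)
  p <- exp(lp - max(lp)); p <- p / sum(p)
  obs <- p[match(n_het, hs)]
  sum(p[p <= obs * (1 + 1e-12)])
}

# two-locus MLE oracle: with allele frequencies fixed by the margins, the
# likelihood has a single free parameter (the minor-minor haplotype
# frequency); maximize it on a dense grid
oracle_two_locus_grid <- function(dos_a, dos_b, res = 1e-6) {
  keep <- !is.na(dos_a) & !is.na(dos_b)
  a <- dos_a[keep]; b <- dos_b[keep]
  n <- length(a)
  pa <- mean(a) / 2; pb <- mean(b) / 2
  lo <- max(0, pa + pb - 1); hi <- min(pa, pb)
  grid <- seq(lo, hi, by = res)
  tab <- table(factor(a, 0:2), factor(b, 0:2))
  ll <- rep(0, length(grid))
  f1 <- grid; f2 <- pa - grid; f3 <- pb - grid; f4 <- 1 - pa - pb + grid
  lg <- function(x) log(pmax(x, 1e-300))
  # per-genotype-class likelihood contributions (phase summed out)
  cl <- list(
    list(0, 0, function() 2 * lg(f4)),
    list(0, 1, function() lg(2 * f3 * f4)),
    list(0, 2, function() 2 * lg(f3)),
    list(1, 0, function() lg(2 * f2 * f4)),
    list(1, 1, function() lg(2 * (f1 * f4 + f2 * f3))),
    list(1, 2, function() lg(2 * f1 * f3)),
    list(2, 0, function() 2 * lg(f2)),
    list(2, 1, function() lg(2 * f1 * f2)),
    list(2, 2, function() 2 * lg(f1)))
  for (c_ in cl) {
    k <- tab[c_[[1]] + 1, c_[[2]] + 1]
    if (k > 0) ll <- ll + k * c_[[3]]()
  }
  grid[which.max(ll)]
}

# multi-locus toy: 4 unambiguous homozygotes + 1 triple heterozygote.
# The MLE lies in the family parameterized by the posterior weights of the
# four diplotype resolutions of the triple het; enumerate that simplex on
# a coarse grid and refine locally (independent of the EM path).
oracle_toy_triple_het <- function() {
  h <- rbind(c(0, 0, 0), c(1, 1, 1), c(1, 1, 0), c(1, 0, 0))
  co <- cohort_from_phased(rbind(h, c(1, 1, 1)), rbind(h, c(0, 0, 0)))
  fixed <- integer(8)
  key <- function(v) sum(v * c(1, 2, 4)) + 1
  for (i in seq_len(nrow(h))) fixed[key(h[i, ])] <- fixed[key(h[i, ])] + 2
  configs <- list(c(key(c(0, 0, 0)), key(c(1, 1, 1))),
                  c(key(c(1, 0, 0)), key(c(0, 1, 1))),
                  c(key(c(0, 1, 0)), key(c(1, 0, 1))),
                  c(key(c(0, 0, 1)), key(c(1, 1, 0))))
  loglik_w <- function(w) {
    f <- fixed
    for (q in 1:4) f[configs[[q]]] <- f[configs[[q]]] + w[q]
    f <- f / 10
    s <- sum(vapply(configs, function(cf) 2 * f[cf[1]] * f[cf[2]], 0))
    sum(fixed * log(pmax(f, 1e-300))) + log(max(s, 1e-300))
  }
  best <- NULL; best_ll <- -Inf
  step <- 0.02
  for (w1 in seq(0, 1, step)) for (w2 in seq(0, 1 - w1, step))
    for (w3 in seq(0, 1 - w1 - w2, step)) {
      w <- c(w1, w2, w3, 1 - w1 - w2 - w3)
      ll <- loglik_w(w)
      if (ll > best_ll) {best_ll <- ll; best <- w}
    }
  for (rstep in c(0.002, 2e-4)) {
    cand <- best
    rng <- seq(-10 * rstep, 10 * rstep, rstep)
    for (d1 in rng) for (d2 in rng) {
      w <- c(cand[1] + d1, cand[2] + d2, cand[3] - d1, cand[4] - d2)
      if (any(w < 0)) next
      ll <- loglik_w(w)
      if (ll > best_ll) {best_ll <- ll; best <- w}
    }
  }
  f_oracle <- fixed
  for (q in 1:4) f_oracle[configs[[q]]] <- f_oracle[configs[[q]]] + best[q]
  list(cohort = co, freqs = f_oracle / 10)
}

# 2x2 cross-product oracle from cell counts
oracle_cross_product <- function(case_exp, case_unexp, ctrl_exp, ctrl_unexp)
  (case_exp * ctrl_unexp) / (case_unexp * ctrl_exp)

# expand a 2x2 table into response/predictor vectors
table_to_data <- function(case_exp, case_unexp, ctrl_exp, ctrl_unexp) {
  y <- rep(c(1, 1, 0, 0), c(case_exp, case_unexp, ctrl_exp, ctrl_unexp))
  x <- rep(c(1, 0, 1, 0), c(case_exp, case_unexp, ctrl_exp, ctrl_unexp))
  list(y = y, x = x)
}

# build a genotype matrix from explicit phased chromosome pairs
cohort_from_phased <- function(h1, h2, snps = NULL, status = NULL) {
  dos <- h1 + h2
  m <- ncol(dos)
  if (is.null(snps)) snps <- make_snps(m)
  geno <- genotype_matrix(dos, snps, sprintf("id%04d", seq_len(nrow(dos))))
  covar <- make_covar(if (is.null(status)) rep(0L, nrow(dos)) else status,
                      ids = geno$samples)
  list(genotypes = geno, covariates = covar)
}
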