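# multi-locus EM, haplotype association, genotype-combination tables

test_that("EM equals direct counting when every sample is homozygous", {
  # diplotypes: mmm/mmm x3, MMM/MMM x4, mmM/mmM x2, MMm... use 3 SNPs
  h <- rbind(matrix(rep(c(1, 1, 1), 3), ncol = 3, byrow = TRUE),
             matrix(rep(c(0, 0, 0), 4), ncol = 3, byrow = TRUE),
             matrix(rep(c(1, 1, 0), 2), ncol = 3, byrow = TRUE),
             matrix(rep(c(0, 0, 1), 1), ncol = 3, byrow = TRUE))
  co <- cohort_from_phased(h, h)
  em <- multi_locus_em(co$genotypes, co$genotypes$snps$snp_id)
  expected <- c(3, 4, 2, 1) / 10
  # haplotype strings use allele letters; compare sorted nonzero freqs
  expect_equal(sort(unname(em$freqs[em$freqs > 0]), decreasing = TRUE),
               sort(expected, decreasing = TRUE), tolerance = 1e-12)
  expect_equal(sum(em$freqs), 1, tolerance = 1e-12)
})

test_that("EM matches grid enumeration on a 5-sample triple-heterozygote toy", {
  toy <- oracle_toy_triple_het()
  em <- multi_locus_em(toy$cohort$genotypes,
                       toy$cohort$genotypes$snps$snp_id)
  expect_lt(max(abs(unname(em$freqs) - toy$freqs)), 2e-3)
})

test_that("frequencies and posteriors normalize; expected counts sum to 2n", {
  set.seed(17)
  for (k in 1:100) {
    co <- random_cohort(60, 3, seed = 2000 + k, maf_range = c(0.15, 0.5))
    em <- multi_locus_em(co$genotypes, co$genotypes$snps$snp_id)
    expect_equal(sum(em$freqs), 1, tolerance = 1e-6)
    wsum <- vapply(em$posterior, function(p) sum(p[, "weight"]), 0)
    expect_true(all(abs(wsum - 1) < 1e-9))
    expect_equal(sum(em$expected), 2 * sum(em$kept), tolerance = 1e-6)
    expect_true(all(abs(rowSums(em$expected) - 2) < 1e-9))
  }
})

test_that("restricted to 2 SNPs, multi_locus_em agrees with two_locus_em", {
  set.seed(29)
  for (k in 1:10) {
    co <- random_cohort(150, 2, seed = 3000 + k)
    em2 <- two_locus_em(snp_dosage(co$genotypes, "s01"),
                        snp_dosage(co$genotypes, "s02"), tol = 1e-12)
    emk <- multi_locus_em(co$genotypes, c("s01", "s02"), tol = 1e-12)
    # bitmask order: 0 = MM, 1 = mM (minor at s01), 2 = Mm, 3 = mm
    expect_lt(max(abs(unname(emk$freqs[c(4, 2, 3, 1)]) -
                        unname(em2$freqs))), 1e-8)
  }
})

test_that("more than 4 SNPs is rejected, too few tested haplotypes too", {
  co <- random_cohort(50, 5, seed = 4)
  expect_error(multi_locus_em(co$genotypes, co$genotypes$snps$snp_id),
               "2-4 SNPs")
  # monomorphic-ish pair where only one haplotype passes the filter
  geno <- genotype_matrix(matrix(0L, 30, 2) + cbind(0L, rep(0L, 30)),
                          make_snps(2), sprintf("id%04d", 1:30))
  cv <- make_covar(rep(c(1L, 0L), 15), ids = geno$samples)
  expect_error(haplotype_association(geno, cv, c("s01", "s02"),
                                     covariates = character(0)),
               "nothing to test")
})

test_that("unambiguous cohort: crude haplotype OR equals the counting oracle", {
  # two SNPs, only haplotypes mm and MM present, all samples homozygous
  # diplotypes -> no phase ambiguity, counts are exact
  h_case <- rbind(matrix(rep(c(1, 1), 30), ncol = 2, byrow = TRUE),
                  matrix(rep(c(0, 0), 70), ncol = 2, byrow = TRUE))
  h_ctrl <- rbind(matrix(rep(c(1, 1), 10), ncol = 2, byrow = TRUE),
                  matrix(rep(c(0, 0), 90), ncol = 2, byrow = TRUE))
  co <- cohort_from_phased(rbind(h_case, h_ctrl), rbind(h_case, h_ctrl),
                           status = rep(c(1L, 0L), c(100, 100)))
  ht <- haplotype_association(co$genotypes, co$covariates,
                              c("s01", "s02"), covariates = character(0))
  # chromosome counts: cases 60 vs 140, controls 20 vs 180
  tab <- ht$table
  risky <- tab[tab$reason != "reference" & tab$tested, ]
  expect_equal(risky$or_crude, oracle_cross_product(60, 140, 20, 180),
               tolerance = 1e-6)
  # the adjusted OR agrees with an independent numerical MLE of the same
  # expectation-substitution likelihood (optim on a hand-coded loglik)
  y <- co$covariates$status
  x <- snp_dosage(co$genotypes, "s01")  # dosage of the risky haplotype
  nll <- function(b) -sum(y * (b[1] + b[2] * x) -
                            log1p(exp(b[1] + b[2] * x)))
  op <- stats::optim(c(0, 0), nll, method = "BFGS",
                     control = list(reltol = 1e-14))
  expect_equal(unname(risky$or), exp(op$par[2]), tolerance = 1e-6)
})

test_that("haplotypes below min_freq are reported untested without an OR", {
  set.seed(58)
  n <- 1000
  # common haplotypes MM, mM, Mm; rare mm at ~0.006
  labels <- c("MM", "mM", "Mm", "mm")
  pr <- c(0.60, 0.25, 0.144, 0.006)
  draw <- sample(4, 2 * n, TRUE, prob = pr)
  hmat <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))[draw, ]
  h1 <- hmat[seq(1, 2 * n, 2), ]; h2 <- hmat[seq(2, 2 * n, 2), ]
  co <- cohort_from_phased(h1, h2, status = rbinom(n, 1, 0.5))
  ht <- haplotype_association(co$genotypes, co$covariates,
                              c("s01", "s02"), covariates = character(0))
  rare <- ht$table[ht$table$haplotype ==
                     paste0(co$genotypes$snps$allele_minor[1],
                            co$genotypes$snps$allele_minor[2]), ]
  expect_false(rare$tested)
  expect_true(is.na(rare$or))
  expect_match(rare$reason, "freq<")
  expect_gt(rare$freq_cases + rare$freq_controls, 0)
})

test_that("relabeling alleles permutes rows but leaves OR and P invariant", {
  set.seed(64)
  co <- random_cohort(800, 3, seed = 111, maf_range = c(0.2, 0.45))
  ht1 <- haplotype_association(co$genotypes, co$covariates,
                               c("s01", "s02", "s03"))
  co2 <- co
  co2$genotypes$dosages[, 2] <- 2L - co2$genotypes$dosages[, 2]
  sw <- co2$genotypes$snps$allele_minor[2]
  co2$genotypes$snps$allele_minor[2] <- co2$genotypes$snps$allele_major[2]
  co2$genotypes$snps$allele_major[2] <- sw
  ht2 <- haplotype_association(co2$genotypes, co2$covariates,
                               c("s01", "s02", "s03"))
  t1 <- ht1$table[order(ht1$table$haplotype), ]
  t2 <- ht2$table[order(ht2$table$haplotype), ]
  expect_identical(t1$haplotype, t2$haplotype)  # same letter strings
  expect_equal(t1$or, t2$or, tolerance = 1e-6)
  expect_equal(t1$p, t2$p, tolerance = 1e-6)
  expect_equal(ht1$reference, ht2$reference)
})

test_that("combination table: indicator fit reproduces exact cross-products", {
  # construct deterministic counts per joint-genotype cell
  cells <- list(list(d1 = 0L, d2 = 1L, nca = 362L, nco = 535L),
                list(d1 = 0L, d2 = 0L, nca = 439L, nco = 469L),
                list(d1 = 1L, d2 = 1L, nca = 436L, nco = 461L),
                list(d1 = 1L, d2 = 0L, nca = 959L, nco = 865L),
                list(d1 = 2L, d2 = 1L, nca = 47L, nco = 38L),
                list(d1 = 2L, d2 = 0L, nca = 531L, nco = 414L))
  d1 <- d2 <- integer(0); y <- integer(0)
  for (cl in cells) {
    d1 <- c(d1, rep(cl$d1, cl$nca + cl$nco))
    d2 <- c(d2, rep(cl$d2, cl$nca + cl$nco))
    y <- c(y, rep(c(1L, 0L), c(cl$nca, cl$nco)))
  }
  snps <- make_snps(2, minor = c("G", "C"), major = c("A", "G"))
  snps$risk_allele <- c("minor", "major")
  geno <- genotype_matrix(cbind(d1, d2), snps,
                          sprintf("id%05d", seq_along(y)))
  cv <- make_covar(y, ids = geno$samples)
  gc_ <- genotype_combination_association(
    geno, cv, c("s01", "s02"),
    grouping = list(s02 = list("C_" = c(1L, 2L), "GG" = 0L)),
    covariates = character(0), reference = "AA & C_")
  tab <- gc_$table
  top <- tab[tab$combo == "GG & GG", ]
  expect_equal(top$n_case, 531L)
  expect_equal(top$n_control, 414L)
  expect_equal(top$or, oracle_cross_product(531, 362, 414, 535),
               tolerance = 1e-6)
  # ordering follows the risk-allele count
  expect_equal(tab$combo[1], "AA & C_")
  expect_true(!is.unsorted(tab$risk_count))
})

test_that("empty combination cells get counts 0 and no OR", {
  set.seed(81)
  n <- 300
  d1 <- rbinom(n, 2, 0.2); d2 <- rbinom(n, 2, 0.3)
  d1[d1 == 2L] <- 1L  # no homozygous-minor at SNP 1
  geno <- genotype_matrix(cbind(d1, d2), make_snps(2),
                          sprintf("id%04d", 1:n))
  cv <- make_covar(rbinom(n, 1, 0.5), ids = geno$samples)
  gc_ <- genotype_combination_association(geno, cv, c("s01", "s02"),
                                          covariates = character(0))
  empty <- gc_$table[gc_$table$n_case + gc_$table$n_control == 0, ]
  expect_gt(nrow(empty), 0)
  expect_true(all(is.na(empty$or)))
})

test_that("planted additive pair yields risk-ordered combination ORs", {
  pool <- pool_independent(c(g1 = 0.4, g2 = 0.35))
  # well-separated per-allele effects so adjacent grouped combinations
  # differ by more than their standard errors
  cfg <- list(pool = pool,
              model = disease_model(snp_log_or = c(g1 = log(1.25),
                                                   g2 = log(1.60)),
                                    prevalence = 0.05),
              n_cases = 1500, n_controls = 1500)
  ok <- 0L
  n_seeds <- 60
  for (sd in seq_len(n_seeds)) {
    co <- simulate_cohort(cfg, seed = 8100 + sd)
    co$genotypes$snps$risk_allele <- "minor"
    gc_ <- genotype_combination_association(
      co$genotypes, co$covariates, c("g1", "g2"),
      grouping = list(g1 = list("lo" = 0L, "hi" = c(1L, 2L)),
                      g2 = list("lo" = 0L, "hi" = c(1L, 2L))),
      covariates = character(0))
    lor <- log(gc_$table$or)
    lor[gc_$table$combo == gc_$reference] <- 0
    if (!is.unsorted(lor, na.rm = TRUE)) ok <- ok + 1L
  }
  expect_gte(ok / n_seeds, 0.85)
})
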