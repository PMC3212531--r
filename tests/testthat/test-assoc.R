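# logistic engine: cross-product oracles, orientation, conditioning, pooling

test_that("balanced null 2x2 gives estimate exactly 0", {
  d <- table_to_data(50, 50, 50, 50)
  f <- fit_logistic(d$y, cbind(x = d$x))
  expect_equal(unname(f$coef["x"]), 0, tolerance = 1e-12)
})

test_that("binary-predictor OR equals the 2x2 cross-product to 1e-6", {
  d <- table_to_data(30, 70, 10, 90)
  f <- fit_logistic(d$y, cbind(x = d$x))
  expect_equal(unname(exp(f$coef["x"])), oracle_cross_product(30, 70, 10, 90),
               tolerance = 1e-6)
  expect_equal(unname(exp(f$coef["x"])), 3.857142857, tolerance = 1e-6)
  # property: 100 random tables without zero cells
  set.seed(11)
  for (k in 1:100) {
    cc <- sample(5:120, 4, replace = TRUE)
    d <- table_to_data(cc[1], cc[2], cc[3], cc[4])
    f <- fit_logistic(d$y, cbind(x = d$x))
    expect_equal(unname(exp(f$coef["x"])),
                 oracle_cross_product(cc[1], cc[2], cc[3], cc[4]),
                 tolerance = 1e-6, label = paste("table", k))
  }
})

test_that("rank deficiency and separation raise structured errors", {
  d <- table_to_data(30, 70, 10, 90)
  err <- expect_error(
    fit_logistic(d$y, cbind(x = d$x, x2 = d$x)),
    class = "condhap_fit_error")
  expect_match(conditionMessage(err), "x2")
  # perfect separation
  y <- rep(c(1, 0), each = 20)
  x <- rep(c(1, 0), each = 20)
  expect_error(fit_logistic(y, cbind(sep = x)),
               class = "condhap_fit_error")
})

test_that("one_sided_p follows the directional convention", {
  expect_equal(one_sided_p(0.10, +1, +1), 0.05)
  expect_equal(one_sided_p(0.10, -1, +1), 0.95)
  expect_equal(one_sided_p(1.0, +1, +1), 0.5)
  # complement property over random inputs
  set.seed(5)
  p <- runif(50)
  expect_equal(one_sided_p(p, +1, +1) + one_sided_p(p, -1, +1),
               rep(1, 50))
})

test_that("risk-allele orientation: OR >= 1, sign flip exact, P invariant", {
  set.seed(21)
  for (k in 1:20) {
    co <- random_cohort(400, 1, seed = 100 + k)
    r <- snp_association(co$genotypes, co$covariates, "s01")
    expect_gte(r$or_point, 1)
    expect_true(r$risk_allele %in% c("minor", "major"))
    expect_equal(r$or_point, exp(abs(r$beta_minor)))
    # flipping the dosage coding must flip beta exactly and keep P
    co2 <- co
    co2$genotypes$dosages[, 1] <- 2L - co2$genotypes$dosages[, 1]
    r2 <- snp_association(co2$genotypes, co2$covariates, "s01")
    expect_equal(r2$beta_minor, -r$beta_minor, tolerance = 1e-9)
    expect_equal(r2$p_value, r$p_value, tolerance = 1e-9)
    expect_equal(r2$or_point, r$or_point, tolerance = 1e-9)
  }
})

test_that("protective minor allele is reported as major-risk", {
  set.seed(33)
  n <- 2000
  dos <- rbinom(n, 2, 0.3)
  y <- rbinom(n, 1, plogis(-0.5 - 0.5 * dos))  # minor allele protective
  geno <- genotype_matrix(matrix(dos, n, 1), make_snps(1),
                          sprintf("id%04d", 1:n))
  r <- snp_association(geno, make_covar(y, ids = geno$samples), "s01",
                       covariates = character(0))
  expect_equal(r$risk_allele, "major")
  expect_gte(r$or_point, 1)
})

test_that("empty conditioning set reproduces snp_association bit-identically", {
  co <- random_cohort(300, 2, seed = 9)
  a <- snp_association(co$genotypes, co$covariates, "s01")
  b <- conditional_association(co$genotypes, co$covariates, "s01",
                               character(0))
  expect_identical(a, b)
})

test_that("monomorphic SNP and perfect-proxy conditioning behave per contract", {
  n <- 100
  dos <- cbind(rep(0L, n), rbinom(n, 2, 0.3))
  geno <- genotype_matrix(dos, make_snps(2), sprintf("id%04d", 1:n))
  cv <- make_covar(rep(c(1L, 0L), n / 2), ids = geno$samples)
  expect_error(snp_association(geno, cv, "s01", covariates = character(0)),
               "monomorphic")
  # test SNP duplicating a conditioning SNP -> absorbed, not a crash
  dos2 <- cbind(dos[, 2], dos[, 2])
  geno2 <- genotype_matrix(dos2, make_snps(2), sprintf("id%04d", 1:n))
  r <- conditional_association(geno2, cv, "s02", "s01",
                               covariates = character(0))
  expect_true(r$absorbed)
  expect_true(is.na(r$p_value))
})

test_that("pooling two copies of a cohort keeps the OR and shrinks the CI", {
  set.seed(61)
  n <- 800
  dos <- rbinom(n, 2, 0.3)
  y <- rbinom(n, 1, plogis(-0.3 + 0.3 * dos))
  geno <- genotype_matrix(matrix(dos, n, 1), make_snps(1),
                          sprintf("id%04d", 1:n))
  cv <- make_covar(y, age = rnorm(n, 60, 5), sex = rbinom(n, 1, 0.5),
                   ids = geno$samples, study = "S1")
  one <- list(genotypes = geno, covariates = cv)
  cv2 <- cv; cv2$sample_id <- paste0("B", cv2$sample_id); cv2$study <- "S2"
  geno2 <- geno; geno2$samples <- cv2$sample_id
  two <- list(genotypes = geno2, covariates = cv2)
  single <- pooled_association(list(one), "s01")
  pooled <- pooled_association(list(one, two), "s01")
  expect_equal(pooled$or_point, single$or_point, tolerance = 1e-6)
  expect_lt(pooled$ci95[2] - pooled$ci95[1],
            single$ci95[2] - single$ci95[1])
  # degenerate pooling of one cohort equals the plain association
  plain <- snp_association(geno, cv, "s01", covariates = c("age", "sex"))
  expect_equal(single$or_point, plain$or_point, tolerance = 1e-9)
  expect_equal(single$p_value, plain$p_value, tolerance = 1e-9)
})

test_that("study adjustment removes Simpson-style confounding", {
  # study 1: mostly cases, high MAF; study 2: mostly controls, low MAF;
  # no SNP effect anywhere -> unadjusted inflated, adjusted calibrated
  build <- function(seed) {
    set.seed(seed)
    n1 <- 600; n2 <- 600
    d1 <- rbinom(n1, 2, 0.45); d2 <- rbinom(n2, 2, 0.15)
    y1 <- rbinom(n1, 1, 0.8); y2 <- rbinom(n2, 1, 0.2)
    c1 <- list(genotypes = genotype_matrix(matrix(d1, n1, 1), make_snps(1),
                                           sprintf("a%04d", 1:n1)),
               covariates = make_covar(y1, ids = sprintf("a%04d", 1:n1),
                                       study = "S1"))
    c2 <- list(genotypes = genotype_matrix(matrix(d2, n2, 1), make_snps(1),
                                           sprintf("b%04d", 1:n2)),
               covariates = make_covar(y2, ids = sprintf("b%04d", 1:n2),
                                       study = "S2"))
    list(c1 = c1, c2 = c2)
  }
  p_adj <- p_crude <- numeric(40)
  for (k in 1:40) {
    cs <- build(7000 + k)
    p_adj[k] <- pooled_association(list(cs$c1, cs$c2), "s01",
                                   covariates = character(0))$p_value
    # crude: same concatenated fit without the study indicator
    gg <- genotype_matrix(rbind(cs$c1$genotypes$dosages,
                                cs$c2$genotypes$dosages), make_snps(1),
                          c(cs$c1$genotypes$samples,
                            cs$c2$genotypes$samples))
    cvv <- rbind(cs$c1$covariates, cs$c2$covariates)
    p_crude[k] <- snp_association(gg, cvv, "s01",
                                  covariates = character(0))$p_value
  }
  expect_lt(max(p_crude), 1e-3)        # confounding inflates every seed
  expect_gt(median(p_adj), 0.1)        # adjusted P is null-like
  expect_gt(min(p_adj), 1e-4)
})

test_that("pooled analysis detects allele mismatches between studies", {
  n <- 50
  g1 <- genotype_matrix(matrix(rbinom(n, 2, 0.3), n, 1), make_snps(1),
                        sprintf("a%03d", 1:n))
  snps2 <- make_snps(1); snps2$allele_minor <- "T"; snps2$allele_major <- "C"
  g2 <- genotype_matrix(matrix(rbinom(n, 2, 0.3), n, 1), snps2,
                        sprintf("b%03d", 1:n))
  c1 <- list(genotypes = g1,
             covariates = make_covar(rbinom(n, 1, 0.5),
                                     ids = g1$samples, study = "S1"))
  c2 <- list(genotypes = g2,
             covariates = make_covar(rbinom(n, 1, 0.5),
                                     ids = g2$samples, study = "S2"))
  expect_error(pooled_association(list(c1, c2), "s01"), "mismatch")
})

test_that("association TSV round-trips through the package reader", {
  co <- random_cohort(300, 3, seed = 77)
  rs <- lapply(co$genotypes$snps$snp_id, function(s)
    snp_association(co$genotypes, co$covariates, s))
  td <- withr::local_tempdir()
  write_assoc_tsv(rs, file.path(td, "a.tsv"))
  back <- read_assoc_tsv(file.path(td, "a.tsv"))
  expect_equal(nrow(back), 3)
  expect_equal(back$or, vapply(rs, `[[`, 0, "or_point"), tolerance = 1e-9)
})

test_that("recessive coding and LRT flags behave sensibly", {
  set.seed(91)
  n <- 3000
  dos <- rbinom(n, 2, 0.4)
  y <- rbinom(n, 1, plogis(-0.6 + 0.6 * (dos == 2)))  # true recessive
  geno <- genotype_matrix(matrix(dos, n, 1), make_snps(1),
                          sprintf("id%05d", 1:n))
  cv <- make_covar(y, ids = geno$samples)
  rec <- conditional_association(geno, cv, "s01", character(0),
                                 covariates = character(0),
                                 coding = "recessive")
  # the recessive fit estimates the planted homozygote effect
  ci <- sort(c(rec$beta_minor - 1.96 * rec$se,
               rec$beta_minor + 1.96 * rec$se))
  expect_true(ci[1] <= 0.6 && 0.6 <= ci[2])
  # LRT and Wald P agree asymptotically on a well-behaved fit
  wald <- conditional_association(geno, cv, "s01", character(0),
                                  covariates = character(0))
  lrt <- conditional_association(geno, cv, "s01", character(0),
                                 covariates = character(0), test = "lrt")
  expect_equal(lrt$test, "lrt")
  expect_lt(abs(log(lrt$p_value) - log(wald$p_value)), 0.5)
})
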