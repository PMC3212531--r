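#' Pairwise gene-gene interaction test
#'
#' Fits `status ~ snp_a * snp_b + other SNPs + covariates` with additive
#' dosage coding and a dosage-product interaction term (multiplicative
#' odds model). The default test is the two-sided Wald test on the product
#' term; `test = "lrt"` compares against the same model without the
#' product term.
#'
#' @param geno a [genotype_matrix()].
#' @param covar covariate table.
#' @param snp_a,snp_b the interacting pair (must differ).
#' @param other_snps additional SNPs kept in the model as covariates.
#' @param covariates adjustment covariates.
#' @param test `"wald"` (default) or `"lrt"`.
#' @return object of class `interaction_result`: `snp_pair`,
#'   `or_interaction`, `ci95`, `p_value`, `test`, `model_terms`, `n_used`,
#'   `absorbed`.
#' @export
interaction_test_pairwise <- function(geno, covar, snp_a, snp_b,
                                      other_snps = character(0),
                                      covariates = c("age", "sex",
                                                     "pc1", "pc2"),
                                      test = c("wald", "lrt")) {
  test <- match.arg(test)
  if (identical(snp_a, snp_b))
    stop("snp_a and snp_b must differ", call. = FALSE)
  d <- build_design(geno, covar, unique(c(snp_a, snp_b, other_snps)),
                    covariates)
  prod_name <- paste0(snp_a, "*", snp_b)
  Xfull <- cbind(d$X, d$X[, snp_a] * d$X[, snp_b])
  colnames(Xfull)[ncol(Xfull)] <- prod_name
  # absorbed product: no rank gained over the main-effect design
  if (qr(cbind(1, Xfull))$rank == qr(cbind(1, d$X))$rank)
    return(structure(list(snp_pair = c(snp_a, snp_b),
                          or_interaction = NA_real_,
                          ci95 = c(NA_real_, NA_real_),
                          p_value = NA_real_, test = test,
                          model_terms = colnames(Xfull),
                          n_used = length(d$y), absorbed = TRUE,
                          reason = "product term collinear"),
                     class = "interaction_result"))
  fit <- fit_logistic(d$y, Xfull)
  b <- fit$coef[[prod_name]]; se <- fit$se[[prod_name]]
  p <- if (test == "wald") fit$p[[prod_name]] else {
    fit0 <- fit_logistic(d$y, d$X)
    stats::pchisq(2 * (fit$loglik - fit0$loglik), df = 1,
                  lower.tail = FALSE)
  }
  structure(list(snp_pair = c(snp_a, snp_b),
                 or_interaction = exp(b),
                 ci95 = exp(b + c(-1, 1) * stats::qnorm(0.975) * se),
                 p_value = p, test = test,
                 model_terms = colnames(Xfull),
                 n_used = fit$n, absorbed = FALSE),
            class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, ...) {
  cat(sprintf("%s x %s: OR_int=%.3f (%.3f-%.3f)  P=%.3g (%s)  n=%d\n",
              x$snp_pair[1], x$snp_pair[2], x$or_interaction,
              x$ci95[1], x$ci95[2], x$p_value, x$test, x$n_used))
  invisible(x)
}

#' Joint test of all pairwise interactions (full model LRT)
#'
#' Likelihood-ratio test of the model with all `choose(k, 2)`
#' dosage-product terms against the main-effects model, on
#' `choose(k, 2)` degrees of freedom. For `k = 2` this coincides with the
#' pairwise LRT.
#'
#' @inheritParams interaction_test_pairwise
#' @param snps at least two SNP ids.
#' @return list with `p_value`, `df`, `lrt_stat`, `loglik_full`,
#'   `loglik_main`, `n_used`, `model_terms`.
#' @export
interaction_test_full <- function(geno, covar, snps,
                                  covariates = c("age", "sex",
                                                 "pc1", "pc2")) {
  k <- length(snps)
  if (k < 2) stop("need at least 2 SNPs", call. = FALSE)
  d <- build_design(geno, covar, snps, covariates)
  prods <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    prods[[paste0(snps[i], "*", snps[j])]] <- d$X[, snps[i]] * d$X[, snps[j]]
  Xfull <- cbind(d$X, do.call(cbind, prods))
  fit_full <- fit_logistic(d$y, Xfull)
  fit_main <- fit_logistic(d$y, d$X)
  lrt <- 2 * (fit_full$loglik - fit_main$loglik)
  df <- choose(k, 2)
  list(p_value = stats::pchisq(lrt, df = df, lower.tail = FALSE),
       df = df, lrt_stat = lrt,
       loglik_full = fit_full$loglik, loglik_main = fit_main$loglik,
       n_used = fit_full$n, model_terms = colnames(Xfull))
}

#' Interaction power design
#'
#' Bundles the parameters of the two-SNP interaction power simulation. The
#' defaults reconstruct the pooled two-study analysis: 2843 cases, 2842
#' controls, susceptibility-allele frequencies 0.40 and 0.21 (the printed
#' pooled-control minor allele frequencies of the two replicated SNPs),
#' per-allele main-effect odds ratios 1.23 and 1.18 (pooled, mutually
#' conditioned), two-sided alpha 0.05, assumed disease prevalence 5%.
#'
#' @param freqs length-2 allele frequencies of the two (independent) SNPs.
#' @param or_main length-2 per-allele main-effect odds ratios.
#' @param or_int interaction odds ratio on the dosage product.
#' @param n_cases,n_controls case-control sample sizes.
#' @param alpha two-sided significance level.
#' @param prevalence assumed population disease prevalence (sets the
#'   logistic intercept; odds ratios are insensitive to it under
#'   case-control sampling).
#' @param n_replicates Monte-Carlo replicates (>= 100).
#' @param oversample super-population oversampling factor for retrospective
#'   sampling.
#' @return list of class `power_design`.
#' @export
power_design <- function(freqs = c(0.40, 0.21),
                         or_main = c(1.23, 1.18),
                         or_int = 1.20,
                         n_cases = 2843, n_controls = 2842,
                         alpha = 0.05, prevalence = 0.05,
                         n_replicates = 2000, oversample = 1.25) {
  stopifnot(length(freqs) == 2, all(freqs > 0 & freqs < 1),
            length(or_main) == 2, or_int > 0, n_replicates >= 100)
  structure(list(freqs = freqs, or_main = or_main, or_int = or_int,
                 n_cases = n_cases, n_controls = n_controls,
                 alpha = alpha, prevalence = prevalence,
                 n_replicates = n_replicates, oversample = oversample),
            class = "power_design")
}

# intercept giving the target prevalence under the exact two-SNP genotype
# distribution of a power_design
design_intercept <- function(design) {
  b <- log(design$or_main); bi <- log(design$or_int)
  g <- expand.grid(g1 = 0:2, g2 = 0:2)
  w <- stats::dbinom(g$g1, 2, design$freqs[1]) *
    stats::dbinom(g$g2, 2, design$freqs[2])
  eta0 <- b[1] * g$g1 + b[2] * g$g2 + bi * g$g1 * g$g2
  f <- function(b0) sum(w * stats::plogis(b0 + eta0)) - design$prevalence
  if (f(-40) > 0 || f(10) < 0)
    stop("infeasible design: no intercept attains the target prevalence",
         call. = FALSE)
  stats::uniroot(f, c(-40, 10), tol = 1e-10)$root
}

#' Monte-Carlo power of the two-SNP interaction Wald test
#'
#' For each replicate a case-control cohort is drawn under the design's
#' logistic disease model (two independent biallelic SNPs in
#' Hardy-Weinberg proportions, retrospective sampling from an oversampled
#' super-population), the logistic model with both main effects plus the
#' dosage-product term is fitted, and the product term is tested at the
#' two-sided Wald level `alpha`. Power is the rejection fraction, with its
#' binomial Monte-Carlo standard error.
#'
#' @param design a [power_design()].
#' @param seed integer seed (mandatory; the whole run is reproducible).
#' @return list of class `power_estimate`: `power`, `mc_se`,
#'   `n_replicates`, `or_int_target`, `n_cases`, `n_controls`, `alpha`,
#'   `seed`, `mean_or_int` (mean estimated interaction OR across
#'   replicates).
#' @examples
#' \donttest{
#' pe <- power_mc(power_design(or_int = 1.2, n_replicates = 200), seed = 1)
#' pe$power
#' }
#' @export
power_mc <- function(design, seed) {
  stopifnot(inherits(design, "power_design"))
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(seed)
  b0 <- design_intercept(design)
  b <- log(design$or_main); bi <- log(design$or_int)
  ncase <- design$n_cases; nctrl <- design$n_controls
  N <- ceiling(design$oversample *
                 max(ncase / design$prevalence,
                     nctrl / (1 - design$prevalence)))
  zcrit <- stats::qnorm(1 - design$alpha / 2)
  rej <- 0L
  sum_or <- 0
  yy <- rep(c(1, 0), c(ncase, nctrl))
  for (r in seq_len(design$n_replicates)) {
    x1 <- stats::rbinom(N, 2, design$freqs[1])
    x2 <- stats::rbinom(N, 2, design$freqs[2])
    y <- stats::rbinom(N, 1, stats::plogis(b0 + b[1] * x1 + b[2] * x2 +
                                             bi * x1 * x2))
    ci <- which(y == 1L); co <- which(y == 0L)
    if (length(ci) < ncase || length(co) < nctrl)
      stop("super-population produced too few cases or controls; ",
           "increase the oversample factor", call. = FALSE)
    idx <- c(sample(ci, ncase), sample(co, nctrl))
    X <- cbind(1, x1[idx], x2[idx], x1[idx] * x2[idx])
    fit <- suppressWarnings(
      stats::glm.fit(X, yy, family = stats::binomial(),
                     control = stats::glm.control(epsilon = 1e-10,
                                                  maxit = 100)))
    V <- chol2inv(chol(crossprod(X * sqrt(fit$weights))))
    z <- fit$coefficients[4] / sqrt(V[4, 4])
    if (abs(z) > zcrit) rej <- rej + 1L
    sum_or <- sum_or + exp(fit$coefficients[4])
  }
  power <- rej / design$n_replicates
  structure(list(power = power,
                 mc_se = sqrt(power * (1 - power) / design$n_replicates),
                 n_replicates = design$n_replicates,
                 or_int_target = design$or_int,
                 n_cases = ncase, n_controls = nctrl,
                 alpha = design$alpha, seed = seed,
                 mean_or_int = sum_or / design$n_replicates),
            class = "power_estimate")
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf(
    "power = %.3f (mc_se %.3f) to detect OR_int = %.2f at alpha = %g\n",
    x$power, x$mc_se, x$or_int_target, x$alpha))
  cat(sprintf("  %d cases / %d controls, %d replicates, seed %d\n",
              x$n_cases, x$n_controls, x$n_replicates, x$seed))
  invisible(x)
}

#' Monte-Carlo power curve over a grid of interaction ORs
#'
#' Runs [power_mc()] at each value of `or_ints` (independent derived seeds
#' per point) and returns a table suitable for TSV export or plotting.
#'
#' @param design a [power_design()] (its `or_int` is overridden per point).
#' @param or_ints numeric vector of interaction ORs.
#' @param seed integer seed.
#' @return data frame with columns `or_int`, `power`, `mc_se`.
#' @export
power_curve <- function(design, or_ints, seed) {
  stopifnot(length(or_ints) >= 1)
  rows <- lapply(seq_along(or_ints), function(i) {
    d <- design
    d$or_int <- or_ints[i]
    pe <- power_mc(d, seed = derive_seed(seed, i))
    data.frame(or_int = or_ints[i], power = pe$power, mc_se = pe$mc_se)
  })
  do.call(rbind, rows)
}

#' Analytic (Wald, normal-approximation) interaction power
#'
#' Closed-form counterpart of [power_mc()]: the expected information of the
#' product term is computed under the retrospective sampling distribution
#' implied by the design, and power is the normal tail probability of the
#' Wald statistic. Used as an independent cross-check of the Monte-Carlo
#' estimate.
#'
#' @param design a [power_design()].
#' @return power (scalar).
#' @export
power_analytic <- function(design) {
  b0 <- design_intercept(design)
  b <- log(design$or_main); bi <- log(design$or_int)
  g <- expand.grid(g1 = 0:2, g2 = 0:2)
  w <- stats::dbinom(g$g1, 2, design$freqs[1]) *
    stats::dbinom(g$g2, 2, design$freqs[2])
  eta <- b0 + b[1] * g$g1 + b[2] * g$g2 + bi * g$g1 * g$g2
  pg <- stats::plogis(eta)
  pcase <- sum(w * pg)
  wc <- w * pg / pcase
  wn <- w * (1 - pg) / (1 - pcase)
  n <- design$n_cases + design$n_controls
  fc <- design$n_cases / n
  # intercept shift induced by case-control sampling fractions
  b0s <- b0 + log(design$n_cases / pcase) -
    log(design$n_controls / (1 - pcase))
  ps <- stats::plogis(b0s - b0 + eta)
  wmix <- fc * wc + (1 - fc) * wn
  X <- cbind(1, g$g1, g$g2, g$g1 * g$g2)
  J <- t(X) %*% (X * (wmix * ps * (1 - ps)))
  se <- sqrt(solve(J)[4, 4] / n)
  z <- abs(bi) / se
  zc <- stats::qnorm(1 - design$alpha / 2)
  stats::pnorm(z - zc) + stats::pnorm(-z - zc)
}
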