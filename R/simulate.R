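# Synthetic case-control cohorts with block-LD haplotype structure,
# planted causal variants, confounded covariates and retrospective
# (case-control) sampling. The generator is the test bed for every
# analysis stage: it emits a genotype matrix, a covariate table and a
# truth record describing what was planted.

derive_seed <- function(seed, k) {
  s <- (as.numeric(seed) %% 2147483)
  as.integer((s * 997 + k * 104729) %% 2147483647)
}

with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

#' Construct a haplotype pool
#'
#' The pool is the stated LD world of a simulation: `H` ancestral
#' haplotypes over `m` SNPs with frequencies on the simplex, plus a
#' per-adjacent-SNP mosaic switch probability. Individuals receive mosaic
#' chromosomes: the template haplotype is drawn from `frequencies` and
#' re-drawn with probability `switch_prob[j-1]` between SNP `j-1` and `j`,
#' which decays LD geometrically with SNP distance while leaving
#' single-SNP frequencies untouched.
#'
#' @param snps SNP metadata data frame (as in [genotype_matrix()]).
#' @param haplotypes `H x m` 0/1 matrix; 1 = minor allele.
#' @param frequencies length-`H` non-negative weights summing to 1
#'   (within 1e-12).
#' @param switch_prob scalar or length `m - 1` vector of mosaic switch
#'   probabilities in \[0, 0.5\].
#' @return object of class `haplotype_pool`.
#' @export
haplotype_pool <- function(snps, haplotypes, frequencies, switch_prob) {
  haplotypes <- as.matrix(haplotypes)
  m <- nrow(snps)
  if (m == 0) stop("empty pool: no SNPs", call. = FALSE)
  if (ncol(haplotypes) != m)
    stop("haplotype length != number of SNPs", call. = FALSE)
  if (length(frequencies) != nrow(haplotypes))
    stop("one frequency per haplotype required", call. = FALSE)
  if (any(frequencies < 0) || abs(sum(frequencies) - 1) > 1e-12)
    stop("frequencies must be >= 0 and sum to 1 within 1e-12",
         call. = FALSE)
  if (length(switch_prob) == 1) switch_prob <- rep(switch_prob, max(m - 1, 0))
  if (length(switch_prob) != max(m - 1, 0))
    stop("switch_prob must have length 1 or n_snps - 1", call. = FALSE)
  if (any(switch_prob < 0 | switch_prob > 0.5))
    stop("switch_prob must lie in [0, 0.5]", call. = FALSE)
  if (is.null(snps$risk_allele)) snps$risk_allele <- "unset"
  structure(list(type = "mosaic", snps = snps, haplotypes = haplotypes,
                 frequencies = frequencies, switch_prob = switch_prob),
            class = "haplotype_pool")
}

#' Pool of mutually independent SNPs given per-SNP minor allele frequencies
#'
#' Convenience alternative to a mosaic pool when exact independence across
#' all SNPs is wanted (e.g. calibration experiments): each allele copy is
#' an independent Bernoulli draw.
#'
#' @param mafs named numeric vector of minor allele frequencies; names
#'   become snp ids (defaults `snp1...`).
#' @param chrom,bp0,bp_step genomic coordinates given to the SNPs.
#' @return object of class `haplotype_pool` with `type = "independent"`.
#' @export
pool_independent <- function(mafs, chrom = "6", bp0 = 32e6,
                             bp_step = 5000) {
  m <- length(mafs)
  if (m == 0) stop("empty pool: no SNPs", call. = FALSE)
  ids <- names(mafs)
  if (is.null(ids)) ids <- paste0("snp", seq_len(m))
  letters2 <- list(c("G", "A"), c("T", "C"), c("C", "G"), c("A", "T"))
  al <- letters2[(seq_len(m) - 1) %% 4 + 1]
  snps <- data.frame(snp_id = ids, chrom = chrom,
                     bp = as.integer(bp0 + seq_len(m) * bp_step),
                     allele_minor = vapply(al, `[`, "", 1),
                     allele_major = vapply(al, `[`, "", 2),
                     risk_allele = "unset", stringsAsFactors = FALSE)
  structure(list(type = "independent", snps = snps,
                 mafs = stats::setNames(as.numeric(mafs), ids)),
            class = "haplotype_pool")
}

#' @export
print.haplotype_pool <- function(x, ...) {
  cat("<haplotype_pool> type:", x$type, "-", nrow(x$snps), "SNPs")
  if (x$type == "mosaic") cat(",", nrow(x$haplotypes), "haplotypes")
  cat("\n")
  invisible(x)
}

#' Simulate phased haplotype pairs from a pool
#'
#' Each individual receives two independent mosaic chromosomes (rows
#' `2i - 1` and `2i` of the result): the template starts from a
#' frequency-weighted draw and is re-drawn with the switch probability at
#' each adjacent SNP. Output is identical under identical seeds, and
#' appending SNPs to a pool leaves the draws of earlier SNPs unchanged.
#'
#' @param pool a [haplotype_pool()].
#' @param n_individuals number of diploid individuals.
#' @param seed optional integer seed.
#' @return `2 * n_individuals x m` integer 0/1 matrix with snp ids as
#'   column names.
#' @export
simulate_haplotypes <- function(pool, n_individuals, seed = NULL) {
  stopifnot(inherits(pool, "haplotype_pool"), n_individuals >= 1)
  if (!is.null(seed)) set.seed(seed)
  nchr <- 2L * n_individuals
  m <- nrow(pool$snps)
  if (pool$type == "independent") {
    out <- vapply(seq_len(m), function(j)
      stats::rbinom(nchr, 1L, pool$mafs[j]), integer(nchr))
  } else {
    H <- nrow(pool$haplotypes)
    out <- matrix(0L, nchr, m)
    t_idx <- sample.int(H, nchr, replace = TRUE, prob = pool$frequencies)
    out[, 1] <- pool$haplotypes[t_idx, 1]
    if (m > 1) for (j in 2:m) {
      sw <- stats::runif(nchr) < pool$switch_prob[j - 1]
      if (any(sw))
        t_idx[sw] <- sample.int(H, sum(sw), replace = TRUE,
                                prob = pool$frequencies)
      out[, j] <- pool$haplotypes[t_idx, j]
    }
  }
  colnames(out) <- pool$snps$snp_id
  out
}

#' Simulate adjustment covariates
#'
#' Age is normal(65, 10) truncated to \[35, 95\] (inverse-CDF sampling, so
#' the truncation does not distort the interior), sex is Bernoulli(0.6)
#' (1 = male, reflecting the male excess of the disease), and the two
#' ancestry principal components are standard normal.
#'
#' @param n number of individuals.
#' @param seed optional integer seed.
#' @param age_mean,age_sd,age_range age distribution parameters.
#' @param p_male probability of sex = 1.
#' @param study study label for all samples.
#' @return covariate table without `status` (all `NA`).
#' @export
simulate_covariates <- function(n, seed = NULL, age_mean = 65, age_sd = 10,
                                age_range = c(35, 95), p_male = 0.6,
                                study = "SIM1") {
  if (!is.null(seed)) set.seed(seed)
  lo <- stats::pnorm(age_range[1], age_mean, age_sd)
  hi <- stats::pnorm(age_range[2], age_mean, age_sd)
  age <- stats::qnorm(stats::runif(n, lo, hi), age_mean, age_sd)
  data.frame(sample_id = sprintf("S%06d", seq_len(n)),
             status = NA_integer_,
             age = age,
             sex = stats::rbinom(n, 1, p_male),
             pc1 = stats::rnorm(n), pc2 = stats::rnorm(n),
             study = study, stringsAsFactors = FALSE)
}

#' Specify a logistic disease model
#'
#' Log-odds of disease are additive in minor-allele dosage for each listed
#' SNP, in dosage products for listed interactions, in exact-haplotype
#' copy counts for listed haplotype effects, and in covariates. The
#' intercept is either given or solved at simulation time so the
#' super-population prevalence matches `prevalence`.
#'
#' @param snp_log_or named numeric: per-minor-allele log odds ratios.
#' @param interaction_log_or optional data frame with columns `snp_a`,
#'   `snp_b`, `log_or` (effect per dosage product unit).
#' @param haplotype_log_or optional list of `list(snps=, alleles=, log_or=)`
#'   where `alleles` is a 0/1 vector over `snps` (1 = minor); the effect is
#'   per copy of that exact haplotype.
#' @param covariate_log_or named numeric over covariate columns.
#' @param intercept fixed intercept (log-odds), or `NULL` to solve from
#'   `prevalence`.
#' @param prevalence target super-population disease prevalence.
#' @return object of class `disease_model`.
#' @export
disease_model <- function(snp_log_or = numeric(0),
                          interaction_log_or = NULL,
                          haplotype_log_or = NULL,
                          covariate_log_or = numeric(0),
                          intercept = NULL, prevalence = 0.05) {
  stopifnot(all(is.finite(snp_log_or)), all(is.finite(covariate_log_or)))
  structure(list(snp_log_or = snp_log_or,
                 interaction_log_or = interaction_log_or,
                 haplotype_log_or = haplotype_log_or,
                 covariate_log_or = covariate_log_or,
                 intercept = intercept, prevalence = prevalence),
            class = "disease_model")
}

model_eta <- function(model, dosages, phased, covar) {
  n <- nrow(covar)
  eta <- numeric(n)
  for (s in names(model$snp_log_or)) {
    if (!s %in% colnames(dosages))
      stop("disease model references unknown SNP: ", s, call. = FALSE)
    eta <- eta + model$snp_log_or[[s]] * dosages[, s]
  }
  if (!is.null(model$interaction_log_or))
    for (i in seq_len(nrow(model$interaction_log_or))) {
      r <- model$interaction_log_or[i, ]
      eta <- eta + r$log_or * dosages[, r$snp_a] * dosages[, r$snp_b]
    }
  if (!is.null(model$haplotype_log_or))
    for (h in model$haplotype_log_or) {
      hp <- phased[, h$snps, drop = FALSE]
      is_hap <- rowSums(hp == matrix(h$alleles, nrow(hp), length(h$alleles),
                                     byrow = TRUE)) == length(h$alleles)
      cnt <- is_hap[seq(1, nrow(hp), 2)] + is_hap[seq(2, nrow(hp), 2)]
      eta <- eta + h$log_or * cnt
    }
  for (cn in names(model$covariate_log_or))
    eta <- eta + model$covariate_log_or[[cn]] * as.numeric(covar[[cn]])
  eta
}

#' Draw disease status and retrospectively sample a case-control cohort
#'
#' Status is Bernoulli under the logistic model over the super-population,
#' then exactly `n_cases` cases and `n_controls` controls are subsampled
#' without replacement (cases first in the output). With a `NULL` model
#' intercept, the intercept is solved so the realized mean risk equals the
#' model prevalence.
#'
#' @param phased `2N x m` phased 0/1 matrix with snp id column names (from
#'   [simulate_haplotypes()]).
#' @param covar covariate table for the `N` individuals.
#' @param model a [disease_model()].
#' @param n_cases,n_controls target counts.
#' @param seed optional integer seed.
#' @return covariate table of the sampled cohort with `status` filled in
#'   and the super-population row indices in `attr(, "index")`.
#' @export
simulate_phenotypes <- function(phased, covar, model, n_cases, n_controls,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- nrow(covar)
  stopifnot(nrow(phased) == 2 * N)
  dosages <- phased[seq(1, 2 * N, 2), , drop = FALSE] +
    phased[seq(2, 2 * N, 2), , drop = FALSE]
  eta0 <- model_eta(model, dosages, phased, covar)
  b0 <- model$intercept
  if (is.null(b0)) {
    f <- function(b) mean(stats::plogis(b + eta0)) - model$prevalence
    if (f(-50) > 0 || f(50) < 0)
      stop("cannot attain the requested prevalence", call. = FALSE)
    b0 <- stats::uniroot(f, c(-50, 50), tol = 1e-9)$root
  }
  y <- stats::rbinom(N, 1, stats::plogis(b0 + eta0))
  ci <- which(y == 1L); co <- which(y == 0L)
  if (length(ci) < n_cases || length(co) < n_controls)
    stop("super-population yielded ", length(ci), " cases / ", length(co),
         " controls; need ", n_cases, "/", n_controls,
         " - increase the oversample factor", call. = FALSE)
  idx <- c(sample(ci, n_cases), sample(co, n_controls))
  out <- covar[idx, , drop = FALSE]
  out$status <- rep(c(1L, 0L), c(n_cases, n_controls))
  rownames(out) <- NULL
  attr(out, "index") <- idx
  attr(out, "intercept") <- b0
  out
}

#' Simulate a complete case-control cohort
#'
#' Orchestrates the generator: haplotypes for an oversampled
#' super-population, covariates, optional covariate-allele confounding,
#' logistic phenotypes with retrospective sampling, and assembly into the
#' package's genotype/covariate containers plus a truth record.
#'
#' Randomness is split into named substreams derived from `seed`
#' (haplotypes, covariates, confounding, phenotypes), so e.g. enlarging the
#' SNP panel does not perturb the phenotype draws.
#'
#' @param config list with elements `pool` (a [haplotype_pool()]), `model`
#'   (a [disease_model()]), `n_cases`, `n_controls`, optional `oversample`
#'   (default 1.3) and optional `confounding` (a
#'   `list(snp=, delta=)`: individuals with positive pc1 have the SNP's
#'   minor-allele frequency shifted by `+delta`, those with negative pc1 by
#'   `-delta`, re-drawn independently of the pool's LD).
#' @param seed integer seed (mandatory: cohorts are reproducible).
#' @return list with `genotypes`, `covariates`, `truth` (class
#'   `truth_record`).
#' @export
simulate_cohort <- function(config, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  pool <- config$pool
  model <- config$model
  stopifnot(inherits(pool, "haplotype_pool"),
            inherits(model, "disease_model"))
  if (nrow(pool$snps) == 0) stop("zero SNPs requested", call. = FALSE)
  n_cases <- config$n_cases; n_controls <- config$n_controls
  oversample <- if (is.null(config$oversample)) 1.3 else config$oversample
  prev <- model$prevalence
  N <- ceiling(oversample * max(n_cases / prev, n_controls / (1 - prev)))

  phased <- simulate_haplotypes(pool, N, seed = derive_seed(seed, 1))
  covar <- simulate_covariates(N, seed = derive_seed(seed, 2))

  if (!is.null(config$confounding)) {
    set.seed(derive_seed(seed, 3))
    cf <- config$confounding
    j <- match(cf$snp, pool$snps$snp_id)
    if (is.na(j)) stop("confounding SNP not in pool: ", cf$snp,
                       call. = FALSE)
    base <- if (pool$type == "independent") pool$mafs[[j]]
    else sum(pool$frequencies * pool$haplotypes[, j])
    shift <- ifelse(covar$pc1 > 0, cf$delta, -cf$delta)
    p_ind <- pmin(pmax(base + shift, 0.01), 0.99)
    phased[seq(1, 2 * N, 2), j] <- stats::rbinom(N, 1, p_ind)
    phased[seq(2, 2 * N, 2), j] <- stats::rbinom(N, 1, p_ind)
  }

  sampled <- simulate_phenotypes(phased, covar, model, n_cases, n_controls,
                                 seed = derive_seed(seed, 4))
  idx <- attr(sampled, "index")
  rows <- as.vector(rbind(2 * idx - 1, 2 * idx))
  ph <- phased[rows, , drop = FALSE]
  dosages <- ph[seq(1, nrow(ph), 2), , drop = FALSE] +
    ph[seq(2, nrow(ph), 2), , drop = FALSE]
  geno <- genotype_matrix(dosages, pool$snps, sampled$sample_id)

  inter <- model$interaction_log_or
  if (!is.null(inter)) inter$or <- exp(inter$log_or)
  truth <- structure(
    list(causal_snps = names(model$snp_log_or),
         causal_or = exp(unlist(model$snp_log_or)),
         interaction = inter,
         haplotype_effects = model$haplotype_log_or,
         n_cases = n_cases, n_controls = n_controls,
         prevalence = prev, seed = seed,
         intercept = attr(sampled, "intercept")),
    class = "truth_record")
  list(genotypes = geno, covariates = sampled, truth = truth)
}

#' @export
print.truth_record <- function(x, ...) {
  cat("<truth_record> seed", x$seed, "\n")
  if (length(x$causal_snps))
    cat("  causal:", paste(sprintf("%s (OR %.2f)", x$causal_snps,
                                   x$causal_or), collapse = ", "), "\n")
  cat(sprintf("  %d cases / %d controls, prevalence %.3f\n",
              x$n_cases, x$n_controls, x$prevalence))
  invisible(x)
}

# conditional success probabilities that give Bernoulli(p_m) a target
# correlation r with an anchor Bernoulli(p_a); r is clamped to feasibility
cond_bernoulli <- function(p_m, p_a, r) {
  r_max <- min(sqrt(p_m * (1 - p_a) / (p_a * (1 - p_m))),
               sqrt(p_a * (1 - p_m) / (p_m * (1 - p_a))))
  r <- min(r, 0.999 * r_max)
  list(p1 = p_m + r * sqrt(p_m * (1 - p_m) * (1 - p_a) / p_a),
       p0 = p_m - r * sqrt(p_m * (1 - p_m) * p_a / (1 - p_a)),
       r = r)
}

#' Pool with one causal SNP and proxies at specified r-squared targets
#'
#' Small helper world used to validate the generator: an anchor SNP plus
#' one proxy per entry of `r2_targets`, built from a large equal-frequency
#' haplotype pool with no mosaic switching, so realized LD tracks the
#' targets up to pool-sampling noise.
#'
#' @param maf anchor (and proxy) minor allele frequency.
#' @param r2_targets numeric vector of r2 targets in (0, 1\].
#' @param n_pool number of pool haplotypes (default 4000).
#' @param seed internal construction seed (the pool is part of the stated
#'   world; fixed by default).
#' @return a [haplotype_pool()]; SNP 1 is the anchor (`anchor`), proxies
#'   are `proxy1...` in target order.
#' @export
make_proxy_pool <- function(maf, r2_targets, n_pool = 4000, seed = 991) {
  with_preserved_rng({
    set.seed(seed)
    m <- 1 + length(r2_targets)
    anchor <- stats::rbinom(n_pool, 1, maf)
    cols <- list(anchor = anchor)
    for (i in seq_along(r2_targets)) {
      cb <- cond_bernoulli(maf, maf, sqrt(r2_targets[i]))
      cols[[paste0("proxy", i)]] <-
        stats::rbinom(n_pool, 1, ifelse(anchor == 1, cb$p1, cb$p0))
    }
    haps <- do.call(cbind, cols)
    ids <- colnames(haps)
    letters2 <- list(c("G", "A"), c("T", "C"), c("C", "G"), c("A", "T"))
    al <- letters2[(seq_len(m) - 1) %% 4 + 1]
    snps <- data.frame(snp_id = ids, chrom = "6",
                       bp = as.integer(32e6 + seq_len(m) * 1000),
                       allele_minor = vapply(al, `[`, "", 1),
                       allele_major = vapply(al, `[`, "", 2),
                       risk_allele = "unset", stringsAsFactors = FALSE)
    haplotype_pool(snps, haps, rep(1 / n_pool, n_pool), switch_prob = 0)
  })
}

#' The fixed 107-SNP block-LD world used throughout the test suite
#'
#' Ten haplotype blocks (seven of 11 SNPs, three of 10) spanning ~1 Mb,
#' built from 512 ancestral haplotypes: each block has an anchor SNP and
#' members correlated with it (star-shaped within-block LD, r between 0.35
#' and 0.85), with mosaic switch probability 0.02 within blocks and 0.5 at
#' block boundaries. Two causal SNPs live in distant blocks: `snp028`
#' (MAF 0.40) and `snp082` (MAF 0.20), each flanked by planted proxies at
#' r-squared targets 0.95, 0.85, 0.70 and 0.60. Four rare SNPs
#' (MAF 0.02-0.04) are uncorrelated with everything. MAFs span 0.02-0.46.
#' The pool is built once from a fixed internal seed: it is part of the
#' stated world, and per-run seeds only vary the cohort draws.
#'
#' @return a [haplotype_pool()] of 107 SNPs.
#' @export
pool_two_signal_region <- function() {
  with_preserved_rng({
    set.seed(614093)
    sizes <- c(rep(11L, 7), rep(10L, 3))
    m <- sum(sizes)
    H <- 512L
    block_of <- rep(seq_along(sizes), sizes)
    start <- cumsum(c(1L, sizes))[seq_along(sizes)]
    causal_idx <- c(28L, 82L)   # middles of blocks 3 and 8
    causal_maf <- c(0.40, 0.20)
    proxy_r2 <- c(0.95, 0.85, 0.70, 0.60)

    maf <- numeric(m); corr <- numeric(m)
    anchor_idx <- integer(length(sizes))
    for (b in seq_along(sizes)) {
      ids <- start[b]:(start[b] + sizes[b] - 1L)
      mid <- ids[ceiling(sizes[b] / 2)]
      anchor_idx[b] <- mid
      ci <- match(mid, causal_idx)
      a_maf <- if (!is.na(ci)) causal_maf[ci] else stats::runif(1, 0.08, 0.46)
      maf[mid] <- a_maf; corr[mid] <- 1
      others <- setdiff(ids, mid)
      if (!is.na(ci)) {
        # four flanking proxies at the planted r2 targets
        prox <- mid + c(1L, -1L, 2L, -2L)
        for (q in seq_along(prox)) {
          maf[prox[q]] <- a_maf
          corr[prox[q]] <- sqrt(proxy_r2[q])
        }
        rest <- setdiff(others, prox)
      } else rest <- others
      maf[rest] <- pmin(pmax(a_maf * stats::runif(length(rest), 0.75, 1.3),
                             0.04), 0.47)
      corr[rest] <- stats::runif(length(rest), 0.35, 0.85)
    }
    # four rare, uncorrelated SNPs in non-causal blocks
    rare_idx <- c(3L, 40L, 70L, 101L)
    maf[rare_idx] <- stats::runif(4, 0.02, 0.04)
    corr[rare_idx] <- 0

    haps <- matrix(0L, H, m)
    for (b in seq_along(sizes)) {
      ids <- start[b]:(start[b] + sizes[b] - 1L)
      mid <- anchor_idx[b]
      a <- stats::rbinom(H, 1, maf[mid])
      haps[, mid] <- a
      for (j in setdiff(ids, mid)) {
        cb <- cond_bernoulli(maf[j], maf[mid], corr[j])
        haps[, j] <- stats::rbinom(H, 1, ifelse(a == 1, cb$p1, cb$p0))
      }
    }
    sp <- rep(0.02, m - 1)
    sp[start[-1] - 1L] <- 0.5   # block boundaries
    letters2 <- list(c("G", "A"), c("T", "C"), c("C", "G"), c("A", "T"))
    al <- letters2[(seq_len(m) - 1) %% 4 + 1]
    snps <- data.frame(snp_id = sprintf("snp%03d", seq_len(m)),
                       chrom = "6",
                       bp = as.integer(31.5e6 + seq_len(m) * 9000),
                       allele_minor = vapply(al, `[`, "", 1),
                       allele_major = vapply(al, `[`, "", 2),
                       risk_allele = "unset", stringsAsFactors = FALSE)
    haplotype_pool(snps, haps, rep(1 / H, H), sp)
  })
}

#' Default simulation preset: two independent signals in a 107-SNP region
#'
#' The stated world of the truth-recovery experiments: the
#' [pool_two_signal_region()] region with causal SNPs `snp028` (per-allele
#' OR 1.31) and `snp082` (OR 1.25) — mutually uncorrelated by block
#' construction — 2000 cases / 1986 controls, 5% prevalence, and mildly
#' confounding covariates (age 0.015 log-odds per year, sex 0.25, pc1
#' 0.20).
#'
#' @param n_cases,n_controls cohort sizes.
#' @return config list for [simulate_cohort()].
#' @export
preset_two_signal <- function(n_cases = 2000, n_controls = 1986) {
  list(pool = pool_two_signal_region(),
       model = disease_model(
         snp_log_or = c(snp028 = log(1.31), snp082 = log(1.25)),
         covariate_log_or = c(age = 0.015, sex = 0.25, pc1 = 0.20,
                              pc2 = 0),
         prevalence = 0.05),
       n_cases = n_cases, n_controls = n_controls, oversample = 1.3)
}
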