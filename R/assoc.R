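#' Maximum-likelihood logistic regression on a named design
#'
#' Thin, strict wrapper around iteratively reweighted least squares
#' (`stats::glm.fit`, relative log-likelihood tolerance `1e-10`, up to 100
#' iterations). An intercept is always prepended. Rank-deficient designs
#' and (quasi-)separated fits raise a structured condition of class
#' `condhap_fit_error` naming the offending column instead of returning
#' garbage estimates.
#'
#' @param y binary response vector (0/1), no missing values.
#' @param X numeric matrix of named predictor columns (no intercept), or
#'   `NULL` for an intercept-only model.
#' @return list with `coef`, `se`, `z`, `p` (two-sided Wald), `vcov`,
#'   `loglik`, `n`, `converged`.
#' @examples
#' y <- rep(c(1, 0), c(100, 100))
#' x <- c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90))
#' f <- fit_logistic(y, cbind(exposed = x))
#' exp(f$coef["exposed"])  # 2x2 cross-product ratio: (30*90)/(70*10)
#' @export
fit_logistic <- function(y, X = NULL) {
  y <- as.numeric(y)
  if (anyNA(y)) stop("missing values in response", call. = FALSE)
  if (length(unique(y)) < 2)
    stop_fit("response has a single outcome class", "response")
  Xf <- cbind(`(intercept)` = rep(1, length(y)), X)
  if (anyNA(Xf)) stop("missing values in design", call. = FALSE)
  if (is.null(colnames(Xf)) || any(colnames(Xf) == ""))
    stop("all predictor columns must be named", call. = FALSE)

  qx <- qr(Xf)
  if (qx$rank < ncol(Xf)) {
    dropped <- colnames(Xf)[qx$pivot[(qx$rank + 1L):ncol(Xf)]]
    stop_fit(paste0("rank-deficient design; collinear column(s): ",
                    paste(dropped, collapse = ", ")), dropped)
  }

  fit <- suppressWarnings(
    stats::glm.fit(Xf, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10,
                                                maxit = 100)))
  cf <- fit$coefficients
  w <- fit$weights
  info <- crossprod(Xf * sqrt(w))
  ok <- TRUE
  vc <- tryCatch(chol2inv(chol(info)), error = function(e) {ok <<- FALSE; NULL})
  se <- if (ok) sqrt(diag(vc)) else rep(NA_real_, length(cf))
  huge <- !is.na(se) & (se > 1e3 | abs(cf) > 30)
  if (!fit$converged || !ok || any(huge)) {
    bad <- colnames(Xf)[if (any(huge)) huge else rep(TRUE, ncol(Xf))]
    stop_fit(paste0("non-convergence (possible separation); suspect ",
                    "column(s): ", paste(bad, collapse = ", ")), bad)
  }
  mu <- fit$fitted.values
  ll <- sum(y * log(mu) + (1 - y) * log1p(-mu))
  z <- cf / se
  dimnames(vc) <- list(colnames(Xf), colnames(Xf))
  list(coef = stats::setNames(cf, colnames(Xf)),
       se = stats::setNames(se, colnames(Xf)),
       z = stats::setNames(z, colnames(Xf)),
       p = stats::setNames(2 * stats::pnorm(-abs(z)), colnames(Xf)),
       vcov = vc, loglik = ll, n = length(y), converged = TRUE)
}

stop_fit <- function(msg, columns) {
  stop(structure(class = c("condhap_fit_error", "error", "condition"),
                 list(message = msg, call = NULL, columns = columns)))
}

#' Convert a two-sided P value to a one-sided one
#'
#' Used for directional replication: `p/2` when the observed effect sign
#' matches the hypothesized direction, `1 - p/2` otherwise.
#'
#' @param two_sided_p two-sided P value in \[0, 1\].
#' @param estimate_sign sign of the observed estimate (+1 or -1).
#' @param hypothesized_sign hypothesized direction (+1 or -1).
#' @return one-sided P value.
#' @export
one_sided_p <- function(two_sided_p, estimate_sign, hypothesized_sign) {
  stopifnot(all(two_sided_p >= 0 & two_sided_p <= 1))
  agree <- rep_len(sign(estimate_sign) == sign(hypothesized_sign),
                   length(two_sided_p))
  ifelse(agree, two_sided_p / 2, 1 - two_sided_p / 2)
}

# Build the complete-case analysis frame for one or more SNPs + covariates.
# Returns list(y, X, n_dropped) or signals why nothing can be fitted.
build_design <- function(geno, covar, snp_ids, covariates) {
  cv <- align_covariates(geno, covar)
  cols <- list()
  for (s in snp_ids) cols[[s]] <- snp_dosage(geno, s)
  for (cname in covariates) {
    if (is.null(cv[[cname]]))
      stop("covariate not found: ", cname, call. = FALSE)
    v <- cv[[cname]]
    if (is.character(v) || is.factor(v)) {
      lev <- sort(unique(as.character(v[!is.na(v)])))
      for (l in lev[-1])
        cols[[paste0(cname, ":", l)]] <- as.numeric(as.character(v) == l)
    } else cols[[cname]] <- as.numeric(v)
  }
  X <- do.call(cbind, cols)
  y <- cv$status
  keep <- stats::complete.cases(X) & !is.na(y)
  list(y = y[keep],
       X = X[keep, , drop = FALSE],
       n_dropped = sum(!keep))
}

as_assoc_result <- function(snp_id, fit, term, geno, conditioned_on, sided) {
  b <- fit$coef[[term]]
  se <- fit$se[[term]]
  p <- fit$p[[term]]
  flip <- b < 0  # orient so the reported (risk) allele has OR >= 1
  est <- if (flip) -b else b
  risk_allele <- if (flip) "major" else "minor"
  ci <- exp(est + c(-1, 1) * stats::qnorm(0.975) * se)
  structure(list(snp_id = snp_id,
                 or_point = exp(est),
                 ci95 = ci,
                 p_value = p,
                 sided = sided,
                 beta_minor = b,
                 se = se,
                 risk_allele = risk_allele,
                 conditioned_on = conditioned_on,
                 n_used = fit$n,
                 absorbed = FALSE),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf(
    "%s  OR[%s]=%.3f (%.3f-%.3f)  P=%.3g (%s-sided)%s  n=%d\n",
    x$snp_id, x$risk_allele, x$or_point, x$ci95[1], x$ci95[2],
    x$p_value, x$sided,
    if (length(x$conditioned_on))
      paste0("  | ", paste(x$conditioned_on, collapse = " & ")) else "",
    x$n_used))
  invisible(x)
}

#' Single-SNP covariate-adjusted association
#'
#' Additive (per-minor-allele dosage) logistic regression of case status on
#' one SNP plus adjustment covariates; the reported odds ratio is
#' re-oriented so the risk allele has OR >= 1, with the orientation
#' recorded. P is the two-sided Wald P of the dosage term.
#'
#' @param geno a [genotype_matrix()].
#' @param covar covariate table.
#' @param snp_id SNP to test.
#' @param covariates character vector of covariate column names (default
#'   age, sex and the two ancestry principal components).
#' @return an `assoc_result`: `or_point`, `ci95`, `p_value`, `sided`,
#'   `risk_allele`, `conditioned_on`, `n_used`, plus the signed
#'   minor-allele estimate `beta_minor` and its `se`.
#' @export
snp_association <- function(geno, covar, snp_id,
                            covariates = c("age", "sex", "pc1", "pc2")) {
  conditional_association(geno, covar, snp_id, character(0), covariates)
}

#' Conditional association of a SNP given other SNPs
#'
#' Identical to [snp_association()] except that the dosages of
#' `conditioning_snps` enter the model as additional covariates; the
#' reported P value is the Wald P of the test-SNP term. A test SNP that is
#' collinear with the conditioning set (e.g. a perfect proxy, r2 = 1 in the
#' analysis sample) yields an `absorbed` result rather than an error.
#'
#' @inheritParams snp_association
#' @param conditioning_snps character vector of SNP ids to condition on
#'   (must not contain `snp_id`); empty set reproduces [snp_association()].
#' @param coding `"additive"` (default; 0/1/2 dosage) or `"recessive"`
#'   (indicator of the homozygous-minor genotype) for the *test* SNP;
#'   conditioning SNPs always enter additively.
#' @param test `"wald"` (default) or `"lrt"`: the P value source for the
#'   test-SNP term. Estimates and CIs are always Wald.
#' @return an `assoc_result`; `absorbed = TRUE` (with `NA` statistics) when
#'   the test SNP carries no information given the conditioning set.
#' @export
conditional_association <- function(geno, covar, snp_id, conditioning_snps,
                                    covariates = c("age", "sex",
                                                   "pc1", "pc2"),
                                    coding = c("additive", "recessive"),
                                    test = c("wald", "lrt")) {
  coding <- match.arg(coding)
  test <- match.arg(test)
  stopifnot(length(snp_id) == 1)
  if (snp_id %in% conditioning_snps)
    stop("test SNP appears in the conditioning set", call. = FALSE)
  d <- build_design(geno, covar, c(snp_id, conditioning_snps), covariates)
  if (coding == "recessive")
    d$X[, snp_id] <- as.numeric(d$X[, snp_id] == 2)
  dos <- d$X[, snp_id]
  if (length(unique(dos)) < 2)
    stop("SNP ", snp_id, " is monomorphic in the analysis sample; ",
         "association undefined", call. = FALSE)
  # the test SNP is 'absorbed' when it adds no rank beyond the
  # conditioning terms (e.g. a perfect proxy, r2 = 1 in this sample)
  others <- d$X[, setdiff(colnames(d$X), snp_id), drop = FALSE]
  if (qr(cbind(1, d$X))$rank == qr(cbind(1, others))$rank)
    return(structure(list(snp_id = snp_id, or_point = NA_real_,
                          ci95 = c(NA_real_, NA_real_),
                          p_value = NA_real_, sided = "two",
                          beta_minor = NA_real_, se = NA_real_,
                          risk_allele = NA_character_,
                          conditioned_on = conditioning_snps,
                          n_used = length(d$y), absorbed = TRUE,
                          reason = "collinear with the conditioning set"),
                     class = "assoc_result"))
  fit <- fit_logistic(d$y, d$X)
  res <- as_assoc_result(snp_id, fit, snp_id, geno, conditioning_snps,
                         "two")
  if (test == "lrt") {
    reduced <- d$X[, setdiff(colnames(d$X), snp_id), drop = FALSE]
    fit0 <- fit_logistic(d$y, if (ncol(reduced)) reduced else NULL)
    res$p_value <- stats::pchisq(2 * (fit$loglik - fit0$loglik), df = 1,
                                 lower.tail = FALSE)
    res$test <- "lrt"
  }
  res
}

#' Pooled multi-study association
#'
#' Re-orients every study's dosages to a common minor allele (determined on
#' the pooled sample), concatenates the samples, and runs one logistic fit
#' with indicator covariates for study membership. P values are two-sided.
#'
#' @param cohorts list of cohorts, each a `list(genotypes=, covariates=)`;
#'   the covariate tables' `study` column must distinguish the studies.
#' @param snp_id SNP to test, present in every cohort.
#' @param covariates adjustment covariates (default age and sex, the
#'   pooled-analysis convention); `"study"` indicators are always added.
#' @param conditioning_snps optional SNPs to condition on.
#' @return an `assoc_result`.
#' @export
pooled_association <- function(cohorts, snp_id,
                               covariates = c("age", "sex"),
                               conditioning_snps = character(0)) {
  stopifnot(length(cohorts) >= 1)
  all_snps <- c(snp_id, conditioning_snps)
  # allele consistency and pooled orientation per SNP
  pooled_parts <- lapply(cohorts, function(co) {
    i <- snp_index(co$genotypes, all_snps)
    co$genotypes$snps[i, c("snp_id", "allele_minor", "allele_major")]
  })
  for (s in all_snps) {
    sets <- lapply(pooled_parts, function(p) {
      r <- p[p$snp_id == s, ]
      sort(c(r$allele_minor, r$allele_major))
    })
    if (length(unique(vapply(sets, paste, "", collapse = "/"))) > 1)
      stop("allele mismatch between studies for SNP ", s,
           " (strand/orientation error)", call. = FALSE)
  }
  # pooled minor allele: pick the letter with the lower pooled frequency
  dose_all <- list()
  for (s in all_snps) {
    per <- lapply(cohorts, function(co) {
      d <- snp_dosage(co$genotypes, s)
      minor <- co$genotypes$snps$allele_minor[snp_index(co$genotypes, s)]
      list(d = d, minor = minor)
    })
    # express each study's dosage as count of study 1's minor letter
    ref_minor <- per[[1]]$minor
    d <- unlist(lapply(per, function(x)
      if (identical(x$minor, ref_minor)) x$d else 2L - x$d))
    if (mean(d, na.rm = TRUE) / 2 > 0.5) d <- 2L - d  # pooled orientation
    dose_all[[s]] <- d
  }
  cv <- do.call(rbind, lapply(cohorts, function(co)
    align_covariates(co$genotypes, co$covariates)))
  cols <- dose_all
  for (cname in covariates) cols[[cname]] <- as.numeric(cv[[cname]])
  stud <- as.character(cv$study)
  for (l in sort(unique(stud))[-1])
    cols[[paste0("study:", l)]] <- as.numeric(stud == l)
  X <- do.call(cbind, cols)
  y <- cv$status
  keep <- stats::complete.cases(X) & !is.na(y)
  fit <- fit_logistic(y[keep], X[keep, , drop = FALSE])
  as_assoc_result(snp_id, fit, snp_id, NULL, conditioning_snps, "two")
}

#' Write association results as TSV
#' @param results list of `assoc_result` objects.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_assoc_tsv <- function(results, path) {
  df <- do.call(rbind, lapply(results, function(r) data.frame(
    snp_id = r$snp_id,
    risk_allele = if (is.na(r$or_point)) NA else r$risk_allele,
    or = r$or_point, ci_low = r$ci95[1], ci_high = r$ci95[2],
    p = r$p_value, sided = r$sided,
    conditioned_on = paste(r$conditioned_on, collapse = ","),
    n_used = r$n_used, absorbed = r$absorbed)))
  utils::write.table(df, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Read an association TSV written by [write_assoc_tsv()]
#' @param path file path.
#' @return data frame.
#' @export
read_assoc_tsv <- function(path)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
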