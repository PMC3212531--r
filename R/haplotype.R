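# Haplotypes over k SNPs are encoded as bitmasks of minor-allele copies:
# bit j set means the haplotype carries the minor allele of the j-th SNP in
# snp_ids order. hap_string() renders them as allele letters.

hap_string <- function(mask, snps) {
  k <- nrow(snps)
  paste(vapply(seq_len(k), function(j) {
    if (bitwAnd(mask, bitwShiftL(1L, j - 1L)) > 0L) snps$allele_minor[j]
    else snps$allele_major[j]
  }, ""), collapse = "")
}

# enumerate unordered diplotypes (h1 <= h2) compatible with a dosage vector
compatible_diplotypes <- function(dos) {
  k <- length(dos)
  het <- which(dos == 1L)
  base <- 0L
  for (j in seq_len(k)) if (dos[j] == 2L) base <- bitwOr(base, bitwShiftL(1L, j - 1L))
  if (!length(het)) return(matrix(c(base, base), 1))
  combos <- expand.grid(rep(list(c(0L, 1L)), length(het)))
  h1 <- h2 <- rep(base, nrow(combos))
  for (idx in seq_along(het)) {
    bit <- bitwShiftL(1L, het[idx] - 1L)
    pick <- combos[[idx]] == 1L
    h1[pick] <- bitwOr(h1[pick], bit)
    h2[!pick] <- bitwOr(h2[!pick], bit)
  }
  lo <- pmin(h1, h2); hi <- pmax(h1, h2)
  unique(cbind(lo, hi))
}

#' Multi-SNP haplotype frequencies by EM
#'
#' Expectation-maximisation over all phase configurations consistent with
#' each sample's multi-SNP genotype, for 2 to 4 SNPs (at most 16
#' haplotypes). Samples with a missing genotype at any of the SNPs are
#' dropped (complete-case on the SNP set). Frequencies are estimated on
#' cases and controls combined; per-sample posterior weights over
#' compatible diplotypes are returned for downstream
#' expectation-substitution regression.
#'
#' @param geno a [genotype_matrix()].
#' @param snp_ids 2-4 SNP ids, in the order haplotype strings are written.
#' @param tol,max_iter convergence controls (largest absolute frequency
#'   change below `tol`, default `1e-10`).
#' @return list with `snp_ids`, `snps` (metadata rows), `freqs` (length
#'   `2^k`, named by haplotype string), `posterior` (per retained sample: a
#'   matrix of compatible diplotypes `h1`, `h2` and weight), `expected`
#'   (n x 2^k matrix of posterior-expected haplotype counts per sample,
#'   rows summing to 2), `kept` (logical over cohort samples), `loglik`,
#'   `iterations`, `converged`.
#' @export
multi_locus_em <- function(geno, snp_ids, tol = 1e-10, max_iter = 2000) {
  k <- length(snp_ids)
  if (k < 2 || k > 4)
    stop("multi_locus_em supports 2-4 SNPs (got ", k, ")", call. = FALSE)
  idx <- snp_index(geno, snp_ids)
  D <- geno$dosages[, idx, drop = FALSE]
  kept <- stats::complete.cases(D)
  D <- D[kept, , drop = FALSE]
  n <- nrow(D)
  if (n == 0) stop("no samples complete on the SNP set", call. = FALSE)
  H <- 2L^k

  # collapse identical genotype patterns for speed
  pat_key <- apply(D, 1, paste, collapse = "")
  upat <- !duplicated(pat_key)
  pat_of <- match(pat_key, pat_key[upat])
  pats <- D[upat, , drop = FALSE]
  dips <- lapply(seq_len(nrow(pats)), function(i)
    compatible_diplotypes(pats[i, ]))
  pat_n <- tabulate(pat_of, nbins = nrow(pats))

  f <- rep(1 / H, H)
  loglik <- -Inf
  converged <- FALSE
  it <- 0
  repeat {
    it <- it + 1
    cnt <- numeric(H)
    ll <- 0
    for (i in seq_along(dips)) {
      dp <- dips[[i]]
      pr <- f[dp[, 1] + 1L] * f[dp[, 2] + 1L] * ifelse(dp[, 1] == dp[, 2], 1, 2)
      s <- sum(pr)
      ll <- ll + pat_n[i] * log(max(s, 1e-300))
      w <- if (s > 0) pr / s else rep(1 / nrow(dp), nrow(dp))
      inc <- pat_n[i] * w
      for (r in seq_len(nrow(dp))) {
        cnt[dp[r, 1] + 1L] <- cnt[dp[r, 1] + 1L] + inc[r]
        cnt[dp[r, 2] + 1L] <- cnt[dp[r, 2] + 1L] + inc[r]
      }
    }
    f_new <- cnt / (2 * n)
    delta <- max(abs(f_new - f))
    f <- f_new
    loglik <- c(loglik, ll)
    if (delta < tol) {converged <- TRUE; break}
    if (it >= max_iter) break
  }

  # per-sample posteriors and expected haplotype counts at convergence
  post <- vector("list", nrow(pats))
  expected_pat <- matrix(0, nrow(pats), H)
  for (i in seq_along(dips)) {
    dp <- dips[[i]]
    pr <- f[dp[, 1] + 1L] * f[dp[, 2] + 1L] * ifelse(dp[, 1] == dp[, 2], 1, 2)
    w <- if (sum(pr) > 0) pr / sum(pr) else rep(1 / nrow(dp), nrow(dp))
    post[[i]] <- cbind(h1 = dp[, 1], h2 = dp[, 2], weight = w)
    for (r in seq_len(nrow(dp))) {
      expected_pat[i, dp[r, 1] + 1L] <- expected_pat[i, dp[r, 1] + 1L] + w[r]
      expected_pat[i, dp[r, 2] + 1L] <- expected_pat[i, dp[r, 2] + 1L] + w[r]
    }
  }
  snps <- geno$snps[idx, , drop = FALSE]
  labels <- vapply(0:(H - 1L), hap_string, "", snps = snps)
  expected <- expected_pat[pat_of, , drop = FALSE]
  colnames(expected) <- labels
  list(snp_ids = snp_ids, snps = snps,
       freqs = stats::setNames(f, labels),
       posterior = post[pat_of],
       expected = expected, kept = kept,
       loglik = loglik[-1], iterations = it, converged = converged)
}

#' Haplotype association against a lowest-risk reference
#'
#' Estimates haplotype frequencies over 2-4 SNPs by EM (cases and controls
#' combined), filters haplotypes with combined frequency below `min_freq`
#' (default 0.01; they are reported but marked untested), picks the tested
#' haplotype with the smallest estimated risk as the reference (or a
#' caller-supplied one), and fits one covariate-adjusted logistic model of
#' case status on the posterior-expected dosages of every other tested
#' haplotype. Each tested haplotype's OR, Wald 95% CI and P are relative to
#' the reference. This expectation-substitution approach (regression on
#' expected haplotype counts) is a standard approximation to the full
#' retrospective haplotype likelihood.
#'
#' @param geno a [genotype_matrix()].
#' @param covar covariate table.
#' @param snp_ids 2-4 SNP ids.
#' @param covariates adjustment covariates.
#' @param min_freq combined-frequency inclusion threshold (default 0.01).
#' @param reference optional haplotype string to force as reference.
#' @param sided `"two"` (default) or `"one"`; one-sided P values assume the
#'   directional hypothesis OR > 1 against the reference, the replication
#'   convention.
#' @return an object of class `haplotype_table`: data frame `table` with
#'   one row per haplotype (string, freq_cases, freq_controls, tested, or,
#'   ci_low, ci_high, p, `or_crude` — the unadjusted chromosome-level
#'   cross-product OR vs the reference — and reason), plus `reference`,
#'   `snp_ids`,
#'   `n_chromosomes_cases`, `n_chromosomes_controls`, `freqs_combined`,
#'   and the underlying `em` fit.
#' @export
haplotype_association <- function(geno, covar, snp_ids,
                                  covariates = c("age", "sex", "pc1", "pc2"),
                                  min_freq = 0.01, reference = NULL,
                                  sided = c("two", "one")) {
  sided <- match.arg(sided)
  em <- multi_locus_em(geno, snp_ids)
  cv <- align_covariates(geno, covar)
  status <- cv$status[em$kept]
  ok <- !is.na(status)

  labels <- names(em$freqs)
  # stratum frequencies via posterior-expected counts under the combined EM
  exp_cases <- em$expected[ok & status == 1, , drop = FALSE]
  exp_ctrls <- em$expected[ok & status == 0, , drop = FALSE]
  freq_cases <- colSums(exp_cases) / max(2 * nrow(exp_cases), 1)
  freq_controls <- colSums(exp_ctrls) / max(2 * nrow(exp_ctrls), 1)

  present <- em$freqs > 0
  tested <- em$freqs >= min_freq
  if (sum(tested) < 2)
    stop("fewer than two haplotypes pass min_freq = ", min_freq,
         "; nothing to test", call. = FALSE)

  # assemble covariate columns on the retained samples
  cov_cols <- list()
  for (cname in covariates) {
    v <- cv[[cname]][em$kept]
    if (is.null(v)) stop("covariate not found: ", cname, call. = FALSE)
    cov_cols[[cname]] <- as.numeric(v)
  }
  covX <- if (length(cov_cols)) do.call(cbind, cov_cols) else NULL
  cc <- ok & (if (is.null(covX)) TRUE else stats::complete.cases(covX))

  fit_against <- function(ref_label) {
    terms <- setdiff(labels[tested], ref_label)
    X <- em$expected[cc, terms, drop = FALSE]
    if (!is.null(covX)) X <- cbind(X, covX[cc, , drop = FALSE])
    fit_logistic(status[cc], X)
  }

  if (is.null(reference)) {
    # provisional fit with the most frequent tested haplotype as baseline,
    # then take the lowest-risk (baseline counts as effect 0)
    base <- labels[tested][which.max(em$freqs[tested])]
    pre <- fit_against(base)
    eff <- stats::setNames(rep(0, sum(tested)), labels[tested])
    got <- intersect(names(pre$coef), names(eff))
    eff[got] <- pre$coef[got]
    reference <- names(eff)[which.min(eff)]
  } else if (!(reference %in% labels[tested]))
    stop("requested reference haplotype is not tested: ", reference,
         call. = FALSE)

  fit <- fit_against(reference)
  # crude chromosome-level OR: expected haplotype counts cross-tabulated
  # against the reference haplotype, cases vs controls
  cnt_cases <- colSums(exp_cases)
  cnt_ctrls <- colSums(exp_ctrls)
  ref_idx <- match(reference, labels)
  or_crude <- (cnt_cases / cnt_cases[ref_idx]) /
    (cnt_ctrls / cnt_ctrls[ref_idx])
  rows <- lapply(seq_along(labels), function(h) {
    lab <- labels[h]
    out <- data.frame(haplotype = lab,
                      freq_cases = freq_cases[h],
                      freq_controls = freq_controls[h],
                      tested = tested[h] && present[h],
                      or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                      p = NA_real_, or_crude = NA_real_, reason = "",
                      stringsAsFactors = FALSE)
    if (!present[h]) {out$reason <- "absent"; out$tested <- FALSE; return(out)}
    if (!tested[h]) {out$reason <- sprintf("freq<%.3g", min_freq); return(out)}
    out$or_crude <- or_crude[h]
    if (lab == reference) {out$reason <- "reference"; return(out)}
    b <- fit$coef[[lab]]; se <- fit$se[[lab]]
    out$or <- exp(b)
    out$ci_low <- exp(b - stats::qnorm(0.975) * se)
    out$ci_high <- exp(b + stats::qnorm(0.975) * se)
    p2 <- fit$p[[lab]]
    out$p <- if (sided == "one") one_sided_p(p2, sign(b), +1) else p2
    out
  })
  tab <- do.call(rbind, rows)
  tab <- tab[present[match(tab$haplotype, labels)] | tab$freq_cases > 0 |
               tab$freq_controls > 0, , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, reference = reference, snp_ids = snp_ids,
                 n_chromosomes_cases = 2 * nrow(exp_cases),
                 n_chromosomes_controls = 2 * nrow(exp_ctrls),
                 freqs_combined = em$freqs, sided = sided,
                 n_used = fit$n, em = em),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("<haplotype_table> SNPs:", paste(x$snp_ids, collapse = ", "), "\n")
  cat("  reference:", x$reference, " (lowest risk)\n")
  cat(sprintf("  chromosomes: %d cases / %d controls\n",
              x$n_chromosomes_cases, x$n_chromosomes_controls))
  df <- x$table
  df$or <- round(df$or, 3); df$p <- signif(df$p, 3)
  df$freq_cases <- round(df$freq_cases, 4)
  df$freq_controls <- round(df$freq_controls, 4)
  print(df[, c("haplotype", "freq_cases", "freq_controls", "tested", "or",
               "p", "reason")], row.names = FALSE)
  invisible(x)
}

#' Write a haplotype table as TSV
#' @param ht a `haplotype_table`.
#' @param path output file.
#' @return path, invisibly.
#' @export
write_haplotype_tsv <- function(ht, path) {
  utils::write.table(ht$table, path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}

#' Joint-genotype additive risk table
#'
#' Cross-classifies samples by grouped genotypes at a small SNP set,
#' reports case/control counts per combination, and fits one
#' indicator-coded covariate-adjusted logistic model against a reference
#' combination (by default the one with the fewest risk alleles).
#' Combinations are ordered by total risk-allele count; empty cells are
#' reported with their zero counts and no OR.
#'
#' @param geno a [genotype_matrix()].
#' @param covar covariate table.
#' @param snp_ids SNPs to cross-classify.
#' @param grouping named list, one element per SNP id, each a named list
#'   mapping a group label to the dosages it covers, e.g.
#'   `list(s4 = list("C_" = c(0, 1), "GG" = 2))`. SNPs absent from
#'   `grouping` keep each dosage as its own group (labelled by genotype).
#' @param covariates adjustment covariates.
#' @param risk_dosage named vector giving, per SNP, the per-group risk
#'   allele count used for ordering; defaults to the group's mean dosage of
#'   the SNP's risk allele (minor unless `risk_allele == "major"`).
#' @param reference optional combination label to force as reference.
#' @param min_cell combinations with fewer cases or controls than this are
#'   reported with their counts but excluded from the fit (no OR); guards
#'   the joint model against separation by sparse cells. Default 5.
#' @return object of class `genotype_combo_table`: data frame `table`
#'   (combo, n_case, n_control, or, ci_low, ci_high, p, risk_count), the
#'   `reference` label and `n_used`.
#' @export
genotype_combination_association <- function(geno, covar, snp_ids,
                                             grouping = list(),
                                             covariates = c("age", "sex"),
                                             risk_dosage = NULL,
                                             reference = NULL,
                                             min_cell = 5) {
  idx <- snp_index(geno, snp_ids)
  snps <- geno$snps[idx, , drop = FALSE]
  cv <- align_covariates(geno, covar)

  geno_label <- function(j, d) {
    mn <- snps$allele_minor[j]; mj <- snps$allele_major[j]
    c(paste0(mj, mj), paste0(mn, mj), paste0(mn, mn))[d + 1]
  }
  # per-SNP group assignment and per-group risk-allele count
  assign_group <- function(j) {
    s <- snp_ids[j]
    d <- snp_dosage(geno, s)
    risk_minor <- !identical(snps$risk_allele[j], "major")
    rd <- if (risk_minor) d else 2L - d
    if (!is.null(grouping[[s]])) {
      lab <- rep(NA_character_, length(d))
      grisk <- numeric(0)
      for (g in names(grouping[[s]])) {
        lab[d %in% grouping[[s]][[g]]] <- g
        gr <- grouping[[s]][[g]]
        grisk[g] <- mean(if (risk_minor) gr else 2 - gr)
      }
      if (any(is.na(lab) & !is.na(d)))
        stop("grouping for ", s, " does not cover all observed genotypes",
             call. = FALSE)
      list(lab = lab, risk = grisk)
    } else {
      lab <- geno_label(j, d)
      grisk <- stats::setNames(
        if (risk_minor) 0:2 else 2:0, geno_label(j, 0:2))
      list(lab = lab, risk = grisk)
    }
  }
  parts <- lapply(seq_along(snp_ids), assign_group)
  labs <- lapply(parts, `[[`, "lab")
  keep <- Reduce(`&`, lapply(labs, function(l) !is.na(l))) & !is.na(cv$status)
  combo <- do.call(paste, c(lapply(labs, function(l) l), sep = " & "))

  # all possible combos (including empty cells), ordered by risk count
  grids <- expand.grid(lapply(parts, function(p) names(p$risk)),
                       stringsAsFactors = FALSE)
  combo_all <- do.call(paste, c(grids, sep = " & "))
  risk_count <- rowSums(mapply(function(col, p) p$risk[col],
                               grids, parts))
  ord <- order(risk_count, combo_all)
  combo_all <- combo_all[ord]; risk_count <- risk_count[ord]

  n_case <- vapply(combo_all, function(cb)
    sum(keep & combo == cb & cv$status == 1), 0L)
  n_control <- vapply(combo_all, function(cb)
    sum(keep & combo == cb & cv$status == 0), 0L)

  nonempty <- n_case + n_control > 0
  fittable <- n_case >= min_cell & n_control >= min_cell
  if (is.null(reference)) reference <- combo_all[fittable][1]
  if (is.na(reference) || !reference %in% combo_all[nonempty])
    stop("reference combination has no samples: ", reference, call. = FALSE)

  cov_cols <- lapply(covariates, function(cn) as.numeric(cv[[cn]]))
  covX <- if (length(cov_cols)) do.call(cbind, cov_cols) else NULL
  if (!is.null(covX)) colnames(covX) <- covariates
  cc <- keep & (if (is.null(covX)) TRUE else stats::complete.cases(covX)) &
    combo %in% c(combo_all[fittable])
  terms <- setdiff(combo_all[fittable], reference)
  X <- vapply(terms, function(cb) as.numeric(combo[cc] == cb),
              numeric(sum(cc)))
  if (!is.null(covX)) X <- cbind(X, covX[cc, , drop = FALSE])
  fit <- fit_logistic(cv$status[cc], X)

  rows <- data.frame(combo = combo_all, n_case = n_case,
                     n_control = n_control, or = NA_real_,
                     ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                     risk_count = risk_count, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(rows))) {
    cb <- rows$combo[i]
    if (cb %in% terms) {
      b <- fit$coef[[cb]]; se <- fit$se[[cb]]
      rows$or[i] <- exp(b)
      rows$ci_low[i] <- exp(b - stats::qnorm(0.975) * se)
      rows$ci_high[i] <- exp(b + stats::qnorm(0.975) * se)
      rows$p[i] <- fit$p[[cb]]
    }
  }
  rownames(rows) <- NULL
  structure(list(table = rows, reference = reference, n_used = fit$n),
            class = "genotype_combo_table")
}

#' @export
print.genotype_combo_table <- function(x, ...) {
  cat("<genotype_combo_table> reference:", x$reference, "\n")
  df <- x$table
  df$or <- round(df$or, 3); df$p <- signif(df$p, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a genotype-combination table as TSV
#' @param gc a `genotype_combo_table`.
#' @param path output file.
#' @return path, invisibly.
#' @export
write_combo_tsv <- function(gc, path) {
  utils::write.table(gc$table, path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}
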