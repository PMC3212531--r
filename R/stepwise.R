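#' Step-wise conditional signal selection with survivor pruning
#'
#' The iterative fine-mapping selector. Round 0 ranks all candidates by
#' their unconditioned covariate-adjusted P and selects the most
#' significant SNP. In every later round, each surviving candidate is
#' re-tested conditioned on *all* previously selected SNPs; survivors whose
#' conditional P reaches `threshold` are dropped permanently (no re-entry
#' unless `allow_reentry = TRUE`), and the most significant remaining
#' survivor is selected. The process stops when no survivor is significant.
#' Ties on P are broken by smaller bp, then snp_id, so the trace is
#' deterministic given the cohort. SNPs whose fit fails (separation,
#' collinearity with the selected set) are treated as dropped, with the
#' reason logged in the round table.
#'
#' Candidate pre-filtering (e.g. marginal GWAS P < 1e-3) is the caller's
#' job; [stepwise_select_prefiltered()] is a convenience wrapper that
#' applies it from an unconditioned scan first.
#'
#' @param geno a [genotype_matrix()].
#' @param covar covariate table.
#' @param candidate_snps character vector of candidate SNP ids.
#' @param covariates adjustment covariates.
#' @param threshold significance threshold per round (default 0.05).
#' @param allow_reentry research flag: when `TRUE`, dropped SNPs re-enter
#'   the survivor pool each round instead of being dropped permanently.
#' @return object of class `stepwise_trace`: `rounds` (list; each has
#'   `round`, `selected`, `survivors`, `results` data frame),
#'   `final_selected` (ordered ids), `threshold`, `dropped_reasons`.
#' @export
stepwise_select <- function(geno, covar, candidate_snps,
                            covariates = c("age", "sex", "pc1", "pc2"),
                            threshold = 0.05,
                            allow_reentry = FALSE) {
  res_df <- function(results) {
    do.call(rbind, lapply(results, function(r) data.frame(
      snp_id = r$snp_id, p = r$p_value, or = r$or_point,
      beta_minor = r$beta_minor, absorbed = r$absorbed,
      stringsAsFactors = FALSE)))
  }
  order_by_p <- function(df) {
    bp <- geno$snps$bp[match(df$snp_id, geno$snps$snp_id)]
    df[order(df$p, bp, df$snp_id), , drop = FALSE]
  }
  safe_test <- function(s, sel) {
    tryCatch(conditional_association(geno, covar, s, sel, covariates),
             error = function(e) structure(
               list(snp_id = s, or_point = NA_real_,
                    ci95 = c(NA_real_, NA_real_), p_value = NA_real_,
                    sided = "two", beta_minor = NA_real_, se = NA_real_,
                    risk_allele = NA_character_, conditioned_on = sel,
                    n_used = NA_integer_, absorbed = TRUE,
                    reason = conditionMessage(e)),
               class = "assoc_result"))
  }

  trace <- list(rounds = list(), final_selected = character(0),
                threshold = threshold,
                dropped_reasons = data.frame(snp_id = character(0),
                                             reason = character(0)))
  class(trace) <- "stepwise_trace"
  if (!length(candidate_snps)) return(trace)

  selected <- character(0)
  pool <- candidate_snps
  round_no <- 0
  repeat {
    results <- lapply(pool, safe_test, sel = selected)
    df <- order_by_p(res_df(results))
    ok <- !is.na(df$p)
    for (s in df$snp_id[!ok])
      trace$dropped_reasons <- rbind(
        trace$dropped_reasons,
        data.frame(snp_id = s, reason = "fit failed / absorbed"))
    sig <- ok & df$p < threshold
    survivors <- df$snp_id[sig]
    if (!length(survivors)) {
      trace$rounds[[length(trace$rounds) + 1]] <-
        list(round = round_no, selected = NA_character_,
             survivors = character(0), results = df)
      break
    }
    pick <- survivors[1]
    selected <- c(selected, pick)
    trace$rounds[[length(trace$rounds) + 1]] <-
      list(round = round_no, selected = pick,
           survivors = setdiff(survivors, pick), results = df)
    pool <- if (allow_reentry) setdiff(candidate_snps, selected)
    else setdiff(survivors, pick)
    round_no <- round_no + 1
    if (!length(pool)) break
  }
  trace$final_selected <- selected
  trace
}

#' Apply a marginal prefilter then run [stepwise_select()]
#' @inheritParams stepwise_select
#' @param prefilter_p marginal unconditioned P cutoff (e.g. 1e-3).
#' @return a `stepwise_trace` (the marginal scan is stored as attribute
#'   `marginal`).
#' @export
stepwise_select_prefiltered <- function(geno, covar, candidate_snps,
                                        covariates = c("age", "sex",
                                                       "pc1", "pc2"),
                                        threshold = 0.05,
                                        prefilter_p = 1e-3, ...) {
  marg <- lapply(candidate_snps, function(s)
    tryCatch(snp_association(geno, covar, s, covariates),
             error = function(e) NULL))
  pv <- vapply(marg, function(r) if (is.null(r)) NA_real_ else r$p_value,
               0)
  keep <- candidate_snps[!is.na(pv) & pv < prefilter_p]
  tr <- stepwise_select(geno, covar, keep, covariates, threshold, ...)
  attr(tr, "marginal") <- data.frame(snp_id = candidate_snps, p = pv)
  tr
}

#' @export
print.stepwise_trace <- function(x, ...) {
  cat("<stepwise_trace> threshold:", x$threshold, "\n")
  for (r in x$rounds) {
    cat(sprintf("  round %d: selected %s, %d survivor(s)\n", r$round,
                ifelse(is.na(r$selected), "<none>", r$selected),
                length(r$survivors)))
  }
  cat("  final:", if (length(x$final_selected))
    paste(x$final_selected, collapse = " -> ") else "<empty>", "\n")
  invisible(x)
}

#' Mutual conditioning of a selected SNP set
#'
#' Re-tests each selected SNP conditioned on all the others — the final
#' cross-check that every member of the selected set carries signal
#' independent of the rest.
#'
#' @inheritParams stepwise_select
#' @param selected_snps SNP ids (at least one).
#' @return named list of `assoc_result`, one per SNP.
#' @export
mutual_conditioning <- function(geno, covar, selected_snps,
                                covariates = c("age", "sex",
                                               "pc1", "pc2")) {
  stopifnot(length(selected_snps) >= 1)
  out <- lapply(selected_snps, function(s)
    conditional_association(geno, covar, s, setdiff(selected_snps, s),
                            covariates))
  stats::setNames(out, selected_snps)
}

#' Serialize a stepwise trace: JSON plus one TSV per round
#' @param trace a `stepwise_trace`.
#' @param out_prefix path prefix.
#' @return vector of files written, invisibly.
#' @export
write_stepwise_trace <- function(trace, out_prefix) {
  files <- character(0)
  js <- list(threshold = trace$threshold,
             final_selected = trace$final_selected,
             rounds = lapply(trace$rounds, function(r)
               list(round = r$round, selected = r$selected,
                    survivors = r$survivors,
                    results = r$results)))
  jpath <- paste0(out_prefix, ".json")
  jsonlite::write_json(js, jpath, auto_unbox = TRUE, digits = NA,
                       na = "null")
  files <- c(files, jpath)
  for (r in trace$rounds) {
    tpath <- sprintf("%s_round%d.tsv", out_prefix, r$round)
    utils::write.table(r$results, tpath, quote = FALSE, sep = "\t",
                       row.names = FALSE)
    files <- c(files, tpath)
  }
  invisible(files)
}
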