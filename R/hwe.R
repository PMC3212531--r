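#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test of HWE for a biallelic SNP: given the sample size
#' and the minor-allele count, the P value sums the probabilities of all
#' heterozygote counts whose conditional probability does not exceed that
#' of the observed count. The conditional distribution is computed with the
#' standard ratio recurrence over heterozygote counts, walking outward from
#' the modal count, so no factorials are evaluated.
#'
#' @param n_hom_minor,n_het,n_hom_major observed genotype counts.
#' @return exact two-sided P value in \[0, 1\]; monomorphic samples give 1.
#' @examples
#' hwe_exact_p(3, 4, 3)
#' hwe_exact_p(0, 0, 25)  # monomorphic -> 1
#' @export
hwe_exact_p <- function(n_hom_minor, n_het, n_hom_major) {
  stopifnot(n_hom_minor >= 0, n_het >= 0, n_hom_major >= 0)
  n <- n_hom_minor + n_het + n_hom_major
  if (n == 0) stop("no genotypes", call. = FALSE)
  n_rare <- 2L * n_hom_minor + n_het
  if (n_rare > n) n_rare <- 2L * n - n_rare  # orient to the rarer allele
  if (n_rare == 0L) return(1)
  # feasible heterozygote counts share the parity of the rare-allele count
  h_min <- n_rare %% 2L
  h_max <- if (n_rare <= (2L * n - n_rare)) n_rare else 2L * n - n_rare
  hs <- seq.int(h_min, h_max, by = 2L)
  probs <- numeric(length(hs))
  # start at (unnormalized) 1 from the smallest feasible count, recurse up:
  # P(h + 2) / P(h) = (n_rare - h) * (2n - n_rare - h) /
  #                   ((h + 2) * (h + 1))
  probs[1] <- 1
  if (length(hs) > 1) {
    for (k in seq_len(length(hs) - 1L)) {
      h <- hs[k]
      probs[k + 1L] <- probs[k] *
        (n_rare - h) * (2L * n - n_rare - h) / ((h + 2) * (h + 1))
    }
  }
  probs <- probs / sum(probs)
  obs <- n_het
  p_obs <- probs[match(obs, hs)]
  if (is.na(p_obs)) stop("impossible genotype configuration", call. = FALSE)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}
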