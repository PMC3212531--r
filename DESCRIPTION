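Package: condhap
Title: Conditional Association, Haplotype and Interaction Analysis for
    Case-Control SNP Regions
Version: 1.0.0
Authors@R:
    person("Hana", "Petrova", email = "hana.petrova@example.org",
           role = c("aut", "cre"))
Description: Fine-mapping toolkit for a case-control SNP region: step-wise
    conditional logistic association to separate independent signals,
    EM-based two-locus and multi-locus haplotype frequency estimation with
    D', r-squared and covariate-adjusted haplotype association against a
    lowest-risk reference, joint-genotype additive risk tables, gene-gene
    interaction tests, and Monte-Carlo power estimation for interaction
    odds ratios. Includes a synthetic case-control cohort generator with
    block linkage disequilibrium, planted causal variants and confounded
    covariates, plus PLINK PED/MAP and minimal VCF readers, so every
    analysis stage is testable without restricted genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
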