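---
title: "Methods and design notes for condhap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for condhap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`condhap` packages the standard fine-mapping toolkit for a case-control
SNP region: step-wise conditional logistic association, EM-based LD and
haplotype analysis, joint-genotype risk tables, and interaction testing
with Monte-Carlo power. This vignette records the statistical model, the
tunable parameters and their defaults, what the synthetic-data generator
does and does not emulate, the numerical choices, and the design decisions
taken where the design was genuinely open. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The association model

All association statistics come from one engine, `fit_logistic()`:
maximum-likelihood logistic regression (IRLS, relative log-likelihood
tolerance 1e-10, at most 100 iterations) of case status on named numeric
columns, with an intercept always included. SNPs enter as additive
minor-allele dosages (0/1/2); the default adjustment set is `age`, `sex`,
`pc1`, `pc2` (ancestry principal components are consumed as given
covariates, never derived). The reported test is the two-sided Wald test
on the SNP term — the convention of the common GWAS tooling this workflow
mirrors — with a likelihood-ratio alternative exposed where it matters
(interaction tests); 95% CIs are Wald intervals on the log-OR.

Three contracts keep the engine honest in degenerate corners:

* rank-deficient designs and (quasi-)separated fits raise a structured
  `condhap_fit_error` naming the offending column — never silent garbage;
* a conditional test whose SNP adds no rank beyond the conditioning set
  (a perfect proxy, r² = 1 in the analysis sample) returns an `absorbed`
  result rather than crashing;
* every model is complete-case: a sample is dropped from a fit iff it is
  missing any SNP or covariate *in that model*. Per-fit sample counts are
  reported (`n_used`) and logged by the pipeline.

Odds ratios are re-oriented so the reported (risk) allele has OR ≥ 1; the
orientation is recorded (`risk_allele`), the flip is an exact sign change
of the estimate, and P values are unaffected. One-sided P values for
directional replication use `p/2` when the observed sign matches the
hypothesis and `1 − p/2` otherwise. Pooled multi-study analysis re-orients
all studies to a common minor allele, concatenates samples, and adds study
indicator covariates (default adjustment: age, sex, study), reporting
two-sided P.

## Step-wise conditional selection

`stepwise_select()` ranks candidates by unconditioned P, selects the
minimum, then in each later round re-tests every surviving candidate
conditioned on *all* previously selected SNPs, permanently dropping
survivors with P ≥ `threshold` (default 0.05) and selecting the minimum-P
survivor, until no survivor is significant. Open-design choices:

* **Tie-breaking** at equal P: smaller bp, then lexicographic snp_id —
  determinism over any statistical rationale.
* **Permanent dropping**: a non-survivor never re-enters. A research flag
  `allow_reentry` implements the alternative, off by default.
* **Failed fits** (separation, collinearity) count as dropped with a
  logged reason, mirroring "lost significance" bookkeeping while keeping
  the procedure total.
* **Candidate pre-filtering** (a marginal GWAS cutoff such as P < 1e-3) is
  the caller's job; `stepwise_select_prefiltered()` is the convenience
  wrapper the pipeline uses.

A caution that the test suite quantifies rather than hides: with ~100
candidates, each round performs many hypothesis tests at the 0.05
threshold against conditionally-null SNPs, and a chance survivor's Wald
statistic barely moves as further quasi-independent SNPs enter the
conditioning set, so chance survivors tend to be selected eventually.
Selection of one or two spurious "independent signals" alongside the real
ones is therefore an *expected* behaviour of this procedure at these
sample sizes — which is exactly why the workflow pairs it with mutual
conditioning and replication. The acceptance suite's truth-recovery
criterion (a tag at r² ≥ 0.8 of every planted signal and nothing else in
≥ 90/100 seeds) is asserted as stated and measured honestly; it fails in
roughly half the seeds for three quantified reasons (marginal prefilter
power ≈ 0.75 for the weaker planted signal, winner's curse among planted
proxies, and the multiplicity just described), while the mutual
conditioning half of the criterion passes in 97/100 seeds.

## LD and haplotype estimation

`two_locus_em()` estimates the four two-locus haplotype frequencies from
unphased dosages. Only double heterozygotes are phase-ambiguous; EM starts
at linkage equilibrium (product of allele frequencies) and stops when the
largest frequency change is < 1e-8 or after 1000 iterations. The
likelihood's ambiguity is one-dimensional, and the test suite checks every
EM solution against an independent dense grid search over that single free
parameter, as well as verifying the log-likelihood never decreases.
`ld_pair()` derives D, D′ (with the usual sign-dependent D_max and the
`D = 0 → D′ = 0` convention) and r²; r² is computed from EM haplotype
frequencies, not genotype correlation — the convention of the
Haploview-style values this mirrors. Samples missing either genotype are
excluded pairwise. Variance note: with unphased data, the double
heterozygote carries no information on phase, so the sampling variance of
D under independence is that of *n* phased chromosomes, not 2*n* — the
null-simulation tests use this SE.

`multi_locus_em()` extends the EM to 2–4 SNPs (≤ 16 haplotypes; larger
sets are refused explicitly), enumerating all phase configurations
(2^(h−1) for h heterozygous sites), collapsing identical genotype
patterns, and returning per-sample posterior diplotype weights plus
posterior-expected haplotype counts (rows sum to 2 within 1e-9).
Frequencies for filtering are estimated on cases and controls combined,
because the inclusion rule is defined on the combined sample.

## Haplotype association

`haplotype_association()` marks haplotypes with combined frequency below
`min_freq` (default 0.01) as untested (rows retain their frequencies and a
reason), picks the lowest-risk *tested* haplotype as reference (a
provisional fit against the most common haplotype estimates the effects;
the minimum — baseline included at 0 — becomes the reference, overridable
by argument), and fits one logistic model of status on the
posterior-expected dosages of all other tested haplotypes plus covariates.

This **expectation substitution** (regression on expected haplotype
counts) is a deliberate approximation to the full retrospective joint
maximum likelihood of specialised haplotype software: it is
well-established, transparent, and testable against counting oracles. Two
consequences are documented rather than hidden. First, phase-uncertain
individuals are handled by weighting, which slightly attenuates extreme
effects when ambiguity is high. Second, on phase-unambiguous data the
*individual-level* per-copy OR is not algebraically identical to the naive
2×2 cross-product of chromosome counts (a homozygote contrast relates to
class odds through twice the coefficient); the table therefore also
reports `or_crude`, the chromosome-level cross-product OR, which *is*
exactly the counting quantity, and the adjusted OR is verified in tests
against an independent numerical MLE instead.

For parameter-recovery experiments the reference is fixed (most common
null haplotype): with all non-target haplotypes at equal risk, the planted
OR against any fixed reference equals the planted parameter exactly,
whereas auto-picking the minimum estimated effect adds a selection bias
that is not part of the planted truth. Auto-picking remains the reporting
default and is tested separately.

`genotype_combination_association()` cross-classifies two (or more) SNPs
by grouped genotypes — grouping rules such as collapsing a rare
minor-allele homozygote with heterozygotes (`C_`) are caller-supplied, and
the pipeline auto-collapses when the homozygote class is rare — and fits
indicator-coded combination effects against the lowest-risk-count
reference. Combinations with fewer than `min_cell = 5` cases or controls
are reported with their counts but kept out of the fit, guarding the joint
model against separation by sparse cells.

## The synthetic cohort generator

The generator is a stated world, not a tuning dial; its defaults were
chosen once to emulate the study design the package targets.

* **LD**: a haplotype-mosaic model. A pool holds H ancestral haplotypes
  with frequencies; each chromosome starts from a frequency-weighted
  template and re-draws it with probability `switch_prob` at each adjacent
  SNP, so pool LD decays geometrically with distance while single-SNP
  frequencies are preserved. This gives direct, dependency-free control of
  haplotype frequencies (a coalescent simulator would add realism the
  analyses never consume). An `independent` pool type provides exact
  independence for calibration experiments.
* **The fixed 107-SNP region** (`pool_two_signal_region()`): ten blocks (seven of
  11 SNPs, three of 10) over ~1 Mb, 512 ancestral haplotypes, star-shaped
  within-block LD (members correlated 0.35–0.85 with a block anchor),
  switch probability 0.02 within blocks and 0.5 at boundaries. Two causal
  SNPs sit in distant blocks — MAF 0.40 with per-allele OR 1.31 and MAF
  0.20 with OR 1.25, mutually uncorrelated (realized r² ≤ 0.01) — each
  flanked by planted proxies at r² targets 0.95/0.85/0.70/0.60. Four rare
  SNPs (MAF 0.02–0.04) are uncorrelated with everything; MAFs span
  0.02–0.46. The pool is built from a fixed internal seed: it is part of
  the stated world, and per-run seeds vary only the cohort draws.
* **Covariates**: age ~ Normal(65, 10) truncated to [35, 95] by
  inverse-CDF sampling; sex ~ Bernoulli(0.6); PCs standard normal. Default
  mild confounding in the region preset: log-OR 0.015/year of age, 0.25
  for sex, 0.20 per pc1 unit. An optional coupling shifts one SNP's allele
  frequency by ±delta with the sign of pc1, for confounding experiments.
* **Phenotypes**: retrospective (case-control) sampling — a
  super-population of `oversample × max(n_cases/prev, n_controls/(1−prev))`
  individuals receives Bernoulli status under the logistic model (the
  intercept is solved so realized prevalence is 5%; prevalence is
  immaterial to ORs under outcome-dependent sampling), then exactly
  n_cases/n_controls are drawn without replacement.
* **Reproducibility**: randomness is split into named substreams derived
  from the seed (haplotypes, covariates, confounding, phenotypes), so
  enlarging the SNP panel does not perturb phenotype draws; identical
  seeds give bitwise-identical cohorts.

What the generator does **not** emulate — hence what a green test does not
establish: genotyping error and missingness mechanisms, imputation
uncertainty, realistic demography/coalescent variation in LD, population
substructure beyond a one-dimensional PC coupling, X-chromosome dosage
conventions, and multi-allelic sites. Tests against this world validate
the estimators and the procedure, not the biology of any particular
region.

## Interaction power

`power_mc()` simulates the pooled two-study design: two independent
biallelic SNPs in Hardy-Weinberg proportions, a logistic model with
additive main effects and a multiplicative dosage-product interaction,
retrospective sampling of 2843 cases / 2842 controls, and a two-sided Wald
test on the product term at α = 0.05; power is the rejection fraction over
2000 replicates (MC SE ≈ 0.011 at power 0.5, adequate for two-digit
percentages). A closed-form companion, `power_analytic()`, computes the
expected information of the product term under the retrospective sampling
distribution and agrees with the Monte-Carlo engine within 0.05 at all
tested designs.

One convention in the default design deserves emphasis: `freqs` are
entered as **minor-allele frequencies** (0.40 and 0.21 for the pooled
two-study design), even when a SNP's risk allele is the major one. Power
is quite sensitive to this convention — re-expressing the second SNP by
its risk-allele frequency (0.79) lowers the computed power by 5–8
percentage points across the interesting OR range — because the variance
of the dosage product, hence the information on the interaction term,
depends on which allele is counted. Closed-form power calculators in this
field take the susceptibility-allele frequency as typed, so when
reproducing a quoted power figure the frequency convention must be matched
first; with the minor-allele convention the engine reproduces the
canonical ≈ 42% / 80% / 89% at interaction ORs 1.12 / 1.20 / 1.23 for this
design. Every element of the design is an explicit argument of
`power_design()`, so either convention can be computed deliberately.

## Numerical choices and degenerate inputs

* Logistic IRLS: tolerance 1e-10, 100 iterations; separation detected by
  non-convergence, exploding coefficients (|β| > 30) or SEs (> 1e3).
* Two-locus EM: frequency-change tolerance 1e-8, ≤ 1000 iterations, single
  equilibrium initialization (the 1-D grid oracle in the tests guards
  against spurious optima). Multi-locus EM: 1e-10, ≤ 2000 iterations.
* Exact HWE: conditional distribution of heterozygote counts via the
  outward ratio recurrence (no factorials); the P value sums probabilities
  ≤ the observed one with a 1 + 1e-12 slack against ties; monomorphic
  samples give P = 1. Computed in **controls** by default — the
  conventional QC stratum — with an `"all"` switch, because the source
  convention is not stated.
* PED dialect: whitespace-delimited, missing allele `0`, phenotype 1/2 →
  control/case; minor allele from pooled frequency, ties broken
  alphabetically; monomorphic SNPs keep a placeholder minor letter (`N`).
  A stratum MAF above 0.5 under pooled orientation is flagged, never
  silently re-oriented per stratum.
* Config files are JSON (no YAML parser in the supported environment).

## Known limitations

* Expectation-substitution haplotype ORs are approximate under heavy phase
  ambiguity (no full retrospective joint ML).
* The stepwise selector inherits the multiplicity behaviour discussed
  above; its output is a candidate set for replication, not a verdict.
* No meta-analysis: pooling concatenates raw data with study indicators.
* The VCF reader is deliberately minimal (uncompressed, biallelic, GT
  only); binary PLINK, BGEN and phased formats are out of scope.
* Monte-Carlo power assumes the two interacting SNPs are independent and
  in HWE; LD between them would require the mosaic pool instead.
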