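---
title: "Models and methods behind vitdgxe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vitdgxe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitdgxe)
```

## Scope

`vitdgxe` implements a complete case–control gene–environment analysis
for vitamin D pathway variants and cancer risk: genotype quality
control, EM haplotype estimation with expected-dosage scoring, GC
(vitamin D binding protein) phenotype derivation, a covariate-based
predicted 25(OH)D exposure score, per-allele and per-haplotype
logistic trend models, stratified interaction testing, and
DerSimonian–Laird meta-analysis across two studies. A synthetic
two-study cohort generator provides data with the statistical
structure the analysis assumes, so every stage is testable without any
external download.

## The statistical models

### Per-allele trend model

For each biallelic SNP a trend variable counts the subject's risk
alleles (0, 1, 2). Unconditional logistic regression of case status on
this dosage plus adjustment covariates gives the per-allele odds ratio
`exp(beta)` with a two-sided Wald trend p-value. Fitting is by IRLS
(`glm`) with convergence tolerance 1e-10 and at most 100 iterations;
divergence of any coefficient beyond |beta| > 15 is treated as
separation and returned as a flagged row rather than a numeric
estimate. The matched design of a nested case–control study is handled
the same way the original analyses handle it: unconditional regression
with matching factors as covariates, not a conditional likelihood.

### Haplotype EM and expectation substitution

Haplotypes over a small set of linked SNPs (the VDR 3' end triplet
rs1544410–rs7975232–rs731236, and the GC pair rs4588–rs7041) are not
observable from unphased genotypes. Frequencies are estimated by EM
over the exhaustively enumerated diplotype space (loci are capped at 8
SNPs):

* E-step: posterior probability of each phase-consistent diplotype
  under current frequencies, summing over all compatible completions
  for subjects with missing SNPs (partial genotyping keeps a subject
  in the fit; only subjects missing the entire locus are excluded).
* M-step: each frequency becomes the average expected haplotype count
  divided by two.
* Convergence: largest absolute frequency change below 1e-8, at most
  1000 iterations; the log-likelihood trace is retained and asserted
  non-decreasing in the tests.

The likelihood can have local maxima — the classic case is a sample of
double heterozygotes, where the symmetric frequency vector is a
stationary point between the coupling- and repulsion-phase solutions.
The default start is therefore the linkage-equilibrium product of
observed allele frequencies, plus five random restarts with fixed
sub-seeds, keeping the best final likelihood.

Association uses *expectation substitution*: each subject's expected
count of each haplotype (a real number in [0, 2], summing to 2 across
haplotypes) enters one logistic model as a set of additive covariates,
with the most common haplotype as the omitted reference (ties broken
lexicographically in C collation). Haplotypes below 5% estimated
frequency are pooled into one "rare" column before modelling; the 5%
threshold is applied to frequencies estimated on the pooled
case+control sample of each study, a choice made because the
published analyses do not say which sample their threshold refers to
(it is configurable). Dosages are used as-is, never rounded.

### GC phenotypes and the binding-affinity trend

The two GC coding SNPs define three protein isoforms via haplotypes
(T-T = GC2, G-G = GC1s, G-T = GC1f at rs4588–rs7041). Subjects are
assigned the isoform pair of their *most probable* diplotype — the
alternative of rounding expected dosages is available but not the
default, since the posterior-mode diplotype is well defined even when
dosages are fractional. The six diplotypes carry published 25(OH)D
binding-affinity constants (Ka × 1e-10 /M): GC2-GC2 3.6, GC2-GC1s 4.8,
GC1s-GC1s 6.0, GC2-GC1f 7.4, GC1s-GC1f 8.6, GC1f-GC1f 11.2. Two
models are fitted: indicators against the GC2-GC2 reference, and a
single trend using Ka as a continuous covariate. A non-isoform (T-G)
haplotype above 1% estimated frequency triggers a warning, because in
practice it indicates an allele-coding error rather than a real
haplotype.

### Predicted 25(OH)D score

The exposure is a deterministic linear score over categorized
lifestyle predictors of plasma 25(OH)D: race/ethnicity, BMI, physical
activity, dietary and supplemental vitamin D, alcohol, UV-B flux,
season, age, and (postmenopausal stratum only) hormone-therapy use.
Category boundaries follow the published labels; values are rounded to
the label's decimal precision and then assigned lower-inclusively, the
only convention under which labels like "0 / 0.1–4.9 / 5–9.9"
partition the axis. The per-category weights are not published (they
come from cohort-specific prediction model fits), so the package
ships a plausible default set with the expected signs — vitamin D
intake, activity, alcohol and UV-B increase the score, BMI decreases
it — and every downstream result that matters here (median
dichotomization, stratified ORs, interaction tests) depends only on
the *ranking* of scores, which is invariant to any strictly increasing
reweighting; the tests assert this invariance explicitly.

Scores are dichotomized at the median of the menopause-specific
control distribution of each study; cases are classified against the
control median. Ties at the median go to the low stratum — the
original convention is unstated, so the tie rule is fixed and
documented here. Subjects with any missing score covariate get a
missing stratum and are excluded from stratified analyses and
interaction tests, never defaulted.

### Interaction tests and meta-analysis

Within each study, genotype-by-exposure interaction is tested by the
Wald test of the dosage × high-stratum cross-product in a logistic
model with both main effects. A global haplotype × stratum test pools
individual-level data from both studies, adjusts for study and the
continuous score, and compares the model with all haplotype × stratum
products to the model without them by likelihood ratio (df = number of
product terms).

Study results are pooled with DerSimonian–Laird random effects: fixed
weights $w_i = 1/s_i^2$, Cochran's $Q$, moment estimator
$\tau^2 = \max(0, (Q - (k-1)) / (\sum w_i - \sum w_i^2 / \sum w_i))$,
random-effects weights $1/(s_i^2 + \tau^2)$. Heterogeneity between the
two predicted-25(OH)D strata is the same fixed-weight $Q$ applied to
the two stratum log-ORs (1 df). Stratified summary rows are computed
as DL pools of the two studies' stratum-specific fits, and the
between-strata heterogeneity compares the two pooled stratum
estimates — the published tables present exactly this combination of
within-study Wald interactions and Q-based between-strata tests.

Published summary rows can be consumed directly: `se_from_ci()`
inverts a printed OR and 95% CI to a log-OR standard error via
$SE = (\ln hi - \ln lo) / (2 \times 1.959964)$. The package uses
z = 1.959964 (not 1.96) throughout; when chaining printed 2-decimal
CIs through inversion and pooling, the extra digits reproduce
published 2-decimal results more reliably. Multiplicity handling is a
reporting-layer choice: `bonferroni()` and `bh_fdr()` are provided,
and heterogeneity p-values are never adjusted internally.

## The synthetic cohort generator

`default_sim_config()` encodes the study conditions the analysis
targets: a matched nested study (562 cases / 1,553 controls, emulated
as covariate adjustment rather than 1:k matched sets, since the
analysis model is unconditional regression anyway) and a
frequency-matched population study (1,821 cases / 1,870 controls).
Genetic structure:

* VDR 3' pool: G-C-T 0.48, A-A-C 0.40, G-A-T 0.07, five rare
  haplotypes totalling 0.05 — three common haplotypes plus a 5% rare
  mass, matching the locus this models.
* GC pool: GC1s 0.57, GC2 0.28, GC1f 0.15, no non-isoform haplotype.
* Independent GWAS SNPs in HWE at realistic risk-allele frequencies.

Disease risk follows
`logit P = intercept + sum(beta_g * dosage) + beta_s * high +
sum(beta_gs * dosage * high)`, where `high` flags an above-median
predicted score. Default effects place interaction log-ORs of ln(1.4)
on rs731236 and rs7975232 with slightly protective main effects, and a
main-effect log-OR of ln(0.92) on rs7041 — the stratum-specific
magnitudes this mirrors (ORs near 0.95 low / 1.35 high) are simulation
settings, not reproduction targets, since the underlying
individual-level data are not public. Fixed case/control counts are
drawn from an oversampled population (case–control sampling preserves
ORs; intercepts are not interpretable afterwards). Genotype
missingness is injected completely at random at 5% (7% for rs7975232
in the nested study, mirroring its lower genotyping success rate).
Season comes from a drawn month via the fixed Dec–Feb / Mar–May /
Jun–Aug / Sep–Nov map. A fixed seed makes the whole cohort
byte-identical across runs.

What the generator does *not* emulate: real matching sets, population
substructure linked to allele frequencies (race is drawn independently
of genotype), genotyping batch or plate effects, and recruitment
artifacts. Passing tests therefore demonstrate correctness of the
statistical machinery under the stated model, not robustness to those
real-data complications; in particular, the race adjustment in the
default analysis is exercised but cannot confound by construction.

## Numerical and design choices

* HWE is tested among controls per study with the plain 1-df
  chi-square (no continuity correction); monomorphic SNPs return
  chisq = 0, p = 1 with a flag rather than an error. Exclusion at
  p < 0.05 is a policy with a per-SNP retain override, supporting
  keep-after-cluster-review decisions; HWE p-values are deliberately
  not multiplicity-corrected, matching the plain p < 0.05 exclusion
  language of the analyses this reproduces.
* Missing genotypes use `NA`, never 0, so dosages cannot silently
  deflate; subjects failing 5 or more SNPs are excluded (count is
  configurable, the boundary is "5 of 15 excluded, 4 retained").
* Pairwise LD r² is computed from two-SNP EM haplotype frequencies
  (`r2 = D^2 / (pA qA pB qB)`), making it symmetric and invariant to
  allele relabelling; proxy selection between SNPs declared
  exchangeable (r² at or above 0.79, the smallest value treated as
  interchangeable here) keeps the better call rate, ties going to the
  lexicographically smaller id with a warning.
* All character ordering (alleles, haplotype labels, tie-breaks) uses
  C-collation radix sorting, so results do not depend on the session
  locale.
* Display rounding in written tables is R's round-half-even, with
  full-precision columns always alongside.

## Problem sizes in the test suite

The test suite regenerates everything it needs: EM recovery uses
n = 5,000 subjects from the default VDR pool (frequencies recovered
within 0.01); the exhaustive-likelihood check compares EM to a
0.01-step simplex grid over the haplotypes compatible with the data
(12 subjects or fewer, support of at most 4 haplotypes — the support
restriction is exact, since haplotypes incompatible with every subject
cannot carry mass at the MLE); interaction-test calibration runs
1,000 null replicates at n = 600 with the empirical size checked
against a 99% binomial band around 0.05, and power is estimated at
150 replicates of 1,000 cases/1,000 controls per stratum with a
stratum-OR ratio of 1.4; pipeline smoke tests run two studies of a few
hundred subjects each. These sizes are the package's choice of a
balance between statistical resolution and a suite that runs in well
under a minute for the deterministic parts and a few tens of seconds
for the simulations.

## Known limitations

* Loci are limited to 8 SNPs (exhaustive diplotype enumeration); no
  partition–ligation phasing.
* No conditional logistic likelihood for matched sets.
* DerSimonian–Laird only — no REML or Hartung–Knapp variants, matching
  the method this pipeline standardizes on.
* The shipped score weights are placeholders with plausible signs;
  analyses interpreting the score's *scale* (rather than its ranking)
  must supply externally fitted weights.
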