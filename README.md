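# vitdgxe

Gene–environment analysis of vitamin D pathway variants in
case–control studies of cancer risk.

## The problem

Epidemiologic results on vitamin D receptor (*VDR*) variants and
ovarian cancer risk have been inconsistent, and one plausible reason
is that a genotype's effect depends on the woman's vitamin D status: a
receptor variant may matter only when there is enough circulating
25-hydroxyvitamin D (25(OH)D) for the receptor to respond to. Testing
that hypothesis requires a full pipeline: quality-controlled genotypes
for *VDR* and 25(OH)D-associated GWAS loci, haplotype estimation at the
*VDR* 3' end (rs1544410–rs7975232–rs731236) and at *GC*/VDBP
(rs4588–rs7041), a predicted 25(OH)D exposure score built from
lifestyle determinants of plasma 25(OH)D, stratified association
models, interaction tests, and meta-analysis across studies.

`vitdgxe` implements that pipeline as tested, reusable R functions,
plus a synthetic two-study cohort generator so every stage can be
validated end-to-end without access to cohort data.

## The core statistics

* **Per-allele trend models** — unconditional logistic regression of
  case status on a 0/1/2 risk-allele dosage, adjusted for matching
  factors and race; per-allele OR = exp(β), two-sided Wald trend p.
* **EM haplotype frequencies and expected dosages** — haplotype
  frequencies from unphased genotypes by EM over the enumerated
  diplotype space (missing SNPs handled by summing over compatible
  completions); per-subject expected haplotype counts in [0, 2]
  ("expectation substitution") used as additive regression covariates,
  with sub-5% haplotypes pooled. GC diplotypes map to VDBP isoform
  phenotypes (GC2, GC1s, GC1f) with published binding-affinity
  constants used as a trend variable.
* **Predicted 25(OH)D score** — a deterministic linear score over
  categorized covariates (BMI, activity, dietary/supplemental vitamin
  D, alcohol, race, UV-B flux, season, age, HT use), dichotomized at
  menopause-specific control medians within each study.
* **Interaction and meta-analysis** — within-study Wald tests of
  dosage × stratum cross-products; a pooled likelihood-ratio test for
  global haplotype × stratum interaction; DerSimonian–Laird
  random-effects pooling with Cochran's Q, the moment estimator of
  τ², and Q-based heterogeneity between exposure strata. Printed
  per-study OR (95% CI) rows can be consumed directly via
  SE = (ln hi − ln lo) / (2 × 1.959964).

## Worked example

Pool two published study estimates for one SNP (per A allele of
rs7975232: 1.17, 95% CI 1.02–1.36 in the nested study; 1.07, 95% CI
0.92–1.25 in the population study):

```r
library(vitdgxe)
m <- dl_meta(log(c(1.17, 1.07)),
             c(se_from_ci(1.17, 1.02, 1.36),
               se_from_ci(1.07, 0.92, 1.25)),
             labels = c("nested", "population"))
m
#> DerSimonian-Laird meta-analysis of 2 estimate(s)
#>   pooled OR 1.12 (95% CI 1.01-1.25)
#>   Q = 0.694 (df 1), p_het = 0.405, tau2 = 0
```

The pooled OR of 1.12 says risk rises about 12% per risk allele when
the two studies are combined; Q at 1 df shows no between-study
heterogeneity, so the random-effects pool coincides with the
fixed-effect one (τ² = 0).

Run the whole pipeline on a synthetic two-study cohort (scaled down to
400 cases / 600 controls per study for a quick demonstration; the
generator plants interaction effects of OR ≈ 1.4 on rs731236 and
rs7975232 among high-score women, and a protective rs7041 main
effect):

```r
cfg <- default_sim_config(seed = 42)
for (s in names(cfg$studies)) {
  cfg$studies[[s]]$n_cases <- 400
  cfg$studies[[s]]$n_controls <- 600
}
b <- run_pipeline(cfg)
b$meta[b$meta$term %in% c("rs7975232", "rs731236", "rs7041"),
       c("term", "or", "ci_low", "ci_high", "p_het")]
#>       term        or    ci_low  ci_high     p_het
#>  rs7975232 1.2929677 1.1225993 1.489192 0.2801448
#>   rs731236 1.2433819 1.0903019 1.417955 0.6801168
#>     rs7041 0.9573894 0.8399265 1.091279 0.7106647

b$stratum_heterogeneity[
  b$stratum_heterogeneity$term %in% c("rs7975232", "rs731236", "rs7041"), ]
#>       term       p_het
#>  rs7975232 0.016325007
#>   rs731236 0.000860785
#>     rs7041 0.321657168
```

The marginal meta-analysis picks up the planted VDR 3' signals
(elevated pooled ORs, no between-study heterogeneity), and the
stratum-heterogeneity column flags exactly the two SNPs whose effect
was made to differ between low and high predicted 25(OH)D — rs7041,
whose planted effect is the same in both strata, is correctly quiet.
`write_tables(b, "out/")` renders the bundle as TSV tables with
full-precision and 2-decimal display columns.

A thin CLI wraps the same functions
(`Rscript inst/cli/vitdgxe.R run --seed 7 --out out/`), with
subcommands `simulate`, `qc`, `run`, and `validate-printed`.

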