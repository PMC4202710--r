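Package: vitdgxe
Title: Gene-Environment Analysis of Vitamin D Pathway Variants in
    Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for case-control gene-environment analyses of vitamin D
    pathway variants: genotype quality control (Hardy-Weinberg tests in
    controls, call rates, subject exclusions, linkage-disequilibrium r2 and
    proxy-SNP selection), expectation-maximization estimation of multi-SNP
    haplotype frequencies with expected-dosage scoring and rare-haplotype
    grouping, vitamin D binding protein (GC) phenotype derivation with
    binding-affinity trend coding, a covariate-based predicted
    25-hydroxyvitamin D score with menopause-specific median
    dichotomization, per-allele and per-haplotype logistic trend models,
    stratified interaction tests, and DerSimonian-Laird random-effects
    meta-analysis with Q-statistic heterogeneity. Includes a synthetic
    two-study cohort generator with haplotype-level linkage disequilibrium
    and a configurable genotype-by-exposure interaction for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite,
    vcfR,
    knitr
Config/testthat/edition: 3
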