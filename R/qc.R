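#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test of genotype counts against
#' Hardy-Weinberg proportions, the standard genotyping quality-control
#' check applied to controls. Expected counts come from the estimated
#' risk-allele frequency `p = (2*n_rr2 + n_rr1) / (2n)`; no continuity
#' correction is applied.
#'
#' @param n_rr2 count of risk-allele homozygotes (dosage 2).
#' @param n_rr1 count of heterozygotes (dosage 1).
#' @param n_rr0 count of other-allele homozygotes (dosage 0).
#' @return list with `chisq`, `p_value`, `df` (1), `raf` (risk-allele
#'   frequency), and `monomorphic` flag. A monomorphic SNP gives
#'   `chisq = 0`, `p_value = 1` with the flag set.
#' @examples
#' hwe_test(30, 40, 30)   # chisq = 4, p ~ 0.0455
#' @export
hwe_test <- function(n_rr2, n_rr1, n_rr0) {
  counts <- c(n_rr2, n_rr1, n_rr0)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n == 0) stop("no genotypes")
  p <- (2 * n_rr2 + n_rr1) / (2 * n)
  if (p %in% c(0, 1)) {
    return(list(chisq = 0, p_value = 1, df = 1L, raf = p, monomorphic = TRUE))
  }
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chisq <- sum((counts - expected)^2 / expected)
  list(chisq = chisq,
       p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       df = 1L, raf = p, monomorphic = FALSE)
}

#' Genotyping call rate for one SNP
#'
#' @param geno genotype matrix (subjects x SNPs, dosages 0/1/2 with `NA`
#'   for failed genotyping).
#' @param snp_id column to summarize.
#' @param subset optional logical vector selecting subjects (e.g., one study).
#' @return fraction of non-missing genotypes.
#' @export
call_rate <- function(geno, snp_id, subset = NULL) {
  if (!snp_id %in% colnames(geno)) stop("unknown SNP: ", snp_id)
  x <- geno[, snp_id]
  if (!is.null(subset)) x <- x[subset]
  if (length(x) == 0) stop("empty cohort")
  mean(!is.na(x))
}

#' Exclude subjects with excessive genotyping failure
#'
#' Removes subjects whose number of missing SNPs meets or exceeds the
#' threshold (default 5, i.e., subjects failing genotyping of five or
#' more SNPs are dropped).
#'
#' @param geno genotype matrix with subject rownames.
#' @param threshold minimum number of failed SNPs that triggers exclusion.
#' @return list with `geno` (filtered matrix) and `excluded` (data.frame
#'   of subject id, failed-SNP count, and reason code).
#' @export
exclude_failed_subjects <- function(geno, threshold = 5) {
  stopifnot(threshold >= 1)
  n_fail <- rowSums(is.na(geno))
  drop <- n_fail >= threshold
  excluded <- data.frame(
    subject_id = rownames(geno)[drop],
    n_failed = unname(n_fail[drop]),
    reason = if (any(drop)) "failed_genotyping" else character(0),
    stringsAsFactors = FALSE
  )
  list(geno = geno[!drop, , drop = FALSE], excluded = excluded)
}

#' Risk-allele frequency
#'
#' @param geno genotype dosage matrix.
#' @param snp_id SNP column.
#' @param subset optional logical subject selector (typically controls).
#' @return frequency in \[0, 1\] among non-missing genotypes.
#' @export
risk_allele_freq <- function(geno, snp_id, subset = NULL) {
  if (!snp_id %in% colnames(geno)) stop("unknown SNP: ", snp_id)
  x <- geno[, snp_id]
  if (!is.null(subset)) x <- x[subset]
  x <- x[!is.na(x)]
  if (length(x) == 0) stop("all genotypes missing for ", snp_id)
  sum(x) / (2 * length(x))
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Two-locus haplotype frequencies are estimated by the same EM used for
#' multi-SNP haplotypes ([em_fit()]), then
#' `r2 = D^2 / (pA qA pB qB)` with `D = f(AB) - pA pB`. The result is
#' invariant to which allele is counted at either SNP.
#'
#' @param geno genotype dosage matrix.
#' @param snp_a,snp_b SNP columns.
#' @return r-squared in \[0, 1\].
#' @export
ld_r2 <- function(geno, snp_a, snp_b) {
  for (s in c(snp_a, snp_b)) {
    if (!s %in% colnames(geno)) stop("unknown SNP: ", s)
  }
  g <- geno[, c(snp_a, snp_b), drop = FALSE]
  g <- g[stats::complete.cases(g), , drop = FALSE]
  if (nrow(g) < 2) stop("need at least 2 fully typed subjects")
  p_a <- mean(g[, 1]) / 2
  p_b <- mean(g[, 2]) / 2
  if (p_a %in% c(0, 1) || p_b %in% c(0, 1)) {
    stop("r2 undefined: monomorphic SNP")
  }
  fit <- em_fit(g, alleles = list(c("a", "A"), c("b", "B")))
  # haplotype carrying the counted allele at both SNPs
  idx <- which(fit$hap_bits[, 1] == 1 & fit$hap_bits[, 2] == 1)
  d <- fit$freq[idx] - p_a * p_b
  unname(d^2 / (p_a * (1 - p_a) * p_b * (1 - p_b)))
}

#' Choose which of two highly correlated SNPs to analyze
#'
#' When two SNPs tag the same signal (declared r-squared at or above
#' `r2_min`), the one with the higher genotyping call rate is retained;
#' ties go to the lexicographically smaller id (with a warning).
#'
#' @param snp_pair character vector of two SNP ids.
#' @param call_rates named numeric call rates covering both SNPs.
#' @param declared_r2 the declared r-squared between the pair.
#' @param r2_min minimum r-squared treated as exchangeable (default 0.79).
#' @return the retained SNP id.
#' @export
select_proxy <- function(snp_pair, call_rates, declared_r2, r2_min = 0.79) {
  stopifnot(length(snp_pair) == 2L)
  if (missing(declared_r2) || is.null(declared_r2) || is.na(declared_r2)) {
    stop("no declared r2 for pair ", paste(snp_pair, collapse = "/"))
  }
  if (declared_r2 < r2_min) {
    stop("declared r2 (", declared_r2, ") below exchangeability threshold ",
         r2_min)
  }
  cr <- call_rates[snp_pair]
  if (any(is.na(cr))) stop("call rate missing for pair member")
  if (cr[1] == cr[2]) {
    keep <- csort(snp_pair)[1]
    warning("equal call rates; retaining lexicographically smaller id ", keep)
    return(keep)
  }
  snp_pair[which.max(cr)]
}

#' Run the full genotype QC stage
#'
#' Per SNP and study: HWE chi-square among controls, call rate, and
#' control risk-allele frequency; subjects failing too many SNPs are
#' excluded. SNPs out of HWE (p below `hwe_alpha` in any study) are
#' flagged for exclusion unless named in `hwe_retain` (supporting
#' retain-despite-HWE decisions made after cluster review).
#'
#' @param geno genotype dosage matrix.
#' @param subjects data.frame with `subject_id`, `study`, `status` (1 = case).
#' @param hwe_alpha HWE exclusion threshold (default 0.05).
#' @param subject_fail_threshold see [exclude_failed_subjects()].
#' @param hwe_retain SNP ids to keep despite HWE failure.
#' @return list of class `qc_report`: `snp_table`, `excluded_subjects`,
#'   `excluded_snps`, and the QC'd `geno`.
#' @export
qc_report <- function(geno, subjects, hwe_alpha = 0.05,
                      subject_fail_threshold = 5, hwe_retain = character(0)) {
  stopifnot(all(rownames(geno) == subjects$subject_id))
  ex <- exclude_failed_subjects(geno, subject_fail_threshold)
  geno <- ex$geno
  subjects <- subjects[subjects$subject_id %in% rownames(geno), , drop = FALSE]
  rows <- list()
  for (study in unique(subjects$study)) {
    in_study <- subjects$study == study
    is_ctrl <- in_study & subjects$status == 0
    for (snp in colnames(geno)) {
      g <- geno[is_ctrl, snp]
      g <- g[!is.na(g)]
      h <- if (length(g)) {
        hwe_test(sum(g == 2), sum(g == 1), sum(g == 0))
      } else {
        list(chisq = NA_real_, p_value = NA_real_, raf = NA_real_,
             monomorphic = NA)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = snp, study = study,
        hwe_chisq = h$chisq, hwe_p = h$p_value,
        control_raf = h$raf, monomorphic = h$monomorphic,
        call_rate = call_rate(geno, snp, in_study),
        stringsAsFactors = FALSE
      )
    }
  }
  snp_table <- do.call(rbind, rows)
  fails <- snp_table$snp_id[!is.na(snp_table$hwe_p) &
                              snp_table$hwe_p < hwe_alpha]
  drop_snps <- setdiff(unique(fails), hwe_retain)
  excluded_snps <- data.frame(
    snp_id = drop_snps,
    reason = rep("hwe_failure", length(drop_snps)),
    stringsAsFactors = FALSE)
  structure(list(
    snp_table = snp_table,
    excluded_subjects = ex$excluded,
    excluded_snps = excluded_snps,
    geno = geno[, setdiff(colnames(geno), excluded_snps$snp_id),
                drop = FALSE],
    subjects = subjects
  ), class = "qc_report")
}
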