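# Synthetic two-study case-control generator.
#
# Emulates the statistical structure the downstream analysis assumes:
# haplotype-level LD at a 3-SNP VDR 3' locus and a 2-SNP GC locus,
# independent GWAS SNPs in HWE, lifestyle covariates driving a
# predicted 25(OH)D score, and a logistic disease model with optional
# genotype-by-high-score interaction. Case-control sampling is done by
# oversampling a source population and drawing fixed numbers of cases
# and controls, which preserves odds ratios (intercepts are not
# interpretable afterwards).

#' Construct a haplotype pool
#'
#' @param snp_ids ordered SNP identifiers.
#' @param haplotypes allele strings like `"G-C-T"`, one allele per SNP.
#' @param frequencies haplotype probabilities; must sum to 1 within 1e-12.
#' @return object of class `haplotype_pool` with derived per-SNP
#'   alleles (`alleles[[j]]` sorted, the second being the one counted
#'   in dosage matrices).
#' @export
haplotype_pool <- function(snp_ids, haplotypes, frequencies) {
  if (length(haplotypes) == 0) stop("empty haplotype pool")
  stopifnot(length(haplotypes) == length(frequencies))
  if (any(frequencies < 0 | frequencies > 1) ||
      abs(sum(frequencies) - 1) > 1e-12) {
    stop("frequencies must be probabilities summing to 1")
  }
  if (anyDuplicated(haplotypes)) stop("haplotypes must be distinct")
  mat <- do.call(rbind, strsplit(haplotypes, "-", fixed = TRUE))
  if (ncol(mat) != length(snp_ids)) {
    stop("haplotype length differs from number of SNPs")
  }
  alleles <- lapply(seq_len(ncol(mat)), function(j) {
    a <- csort(unique(mat[, j]))
    if (length(a) > 2) stop("SNP ", snp_ids[j], " is not biallelic")
    if (length(a) == 1) a <- c(a, a)
    a
  })
  structure(list(snp_ids = snp_ids, haplotypes = haplotypes,
                 frequencies = frequencies, hap_mat = mat,
                 alleles = alleles),
            class = "haplotype_pool")
}

#' Default VDR 3' end haplotype pool
#'
#' Three common haplotypes over rs1544410-rs7975232-rs731236 (G-C-T
#' 48%, A-A-C 40%, G-A-T 7%) plus five rare haplotypes totalling 5%,
#' so that downstream grouping yields three named haplotypes and one
#' pooled rare column.
#' @return a `haplotype_pool`.
#' @export
default_vdr_pool <- function() {
  haplotype_pool(
    snp_ids = c("rs1544410", "rs7975232", "rs731236"),
    haplotypes = c("G-C-T", "A-A-C", "G-A-T",
                   "A-C-T", "A-A-T", "G-C-C", "G-A-C", "A-C-C"),
    frequencies = c(0.48, 0.40, 0.07, 0.015, 0.012, 0.010, 0.008, 0.005)
  )
}

#' Default GC (vitamin D binding protein) haplotype pool
#'
#' rs4588-rs7041 isoform haplotypes at frequencies close to those seen
#' in predominantly white populations: GC1s (G-G) 0.57, GC2 (T-T) 0.28,
#' GC1f (G-T) 0.15; the non-isoform T-G haplotype is absent.
#' @return a `haplotype_pool`.
#' @export
default_gc_pool <- function() {
  haplotype_pool(
    snp_ids = c("rs4588", "rs7041"),
    haplotypes = c("G-G", "T-T", "G-T"),
    frequencies = c(0.57, 0.28, 0.15)
  )
}

#' SNP definitions used by the default simulation
#'
#' Risk alleles follow the convention of the analyses this package
#' supports: putatively lower-VDR-activity alleles for VDR SNPs and
#' lower-25(OH)D alleles for the GWAS loci.
#' @return data.frame with `snp_id`, `risk_allele`, `other_allele`,
#'   `locus`.
#' @export
default_snp_defs <- function() {
  data.frame(
    snp_id = c("rs1544410", "rs7975232", "rs731236", "rs2228570",
               "rs11568820", "rs4588", "rs7041", "rs10741657",
               "rs3829251", "rs6013897"),
    risk_allele = c("A", "A", "C", "T", "G", "T", "T", "G", "A", "A"),
    other_allele = c("G", "C", "T", "C", "A", "G", "G", "A", "G", "T"),
    locus = c("vdr3", "vdr3", "vdr3", "vdr", "vdr", "gc", "gc",
              "gwas", "gwas", "gwas"),
    stringsAsFactors = FALSE
  )
}

month_to_season <- function(month) {
  stopifnot(all(month %in% 1:12))
  c("Winter", "Winter", "Spring", "Spring", "Spring", "Summer",
    "Summer", "Summer", "Fall", "Fall", "Fall", "Winter")[month]
}

#' Draw haplotype pairs (diplotypes) under random mating
#'
#' Pairs are drawn independently with probability `f_i * f_j` (ordered
#' pairs; HWE). The genotype at each SNP is the unordered allele pair.
#'
#' @param pool a `haplotype_pool`.
#' @param n number of subjects.
#' @return list: `h1`, `h2` (haplotype indices), `dosage` (n x m counts
#'   of the second sorted allele), `pairs` (n x m allele-pair strings
#'   like `"A/C"`).
#' @export
draw_diplotypes <- function(pool, n) {
  stopifnot(inherits(pool, "haplotype_pool"), n >= 1)
  h1 <- sample.int(length(pool$frequencies), n, replace = TRUE,
                   prob = pool$frequencies)
  h2 <- sample.int(length(pool$frequencies), n, replace = TRUE,
                   prob = pool$frequencies)
  m <- length(pool$snp_ids)
  dosage <- matrix(0L, n, m, dimnames = list(NULL, pool$snp_ids))
  pairs <- matrix("", n, m, dimnames = list(NULL, pool$snp_ids))
  for (j in seq_len(m)) {
    a1 <- pool$hap_mat[h1, j]
    a2 <- pool$hap_mat[h2, j]
    counted <- pool$alleles[[j]][2]
    dosage[, j] <- (a1 == counted) + (a2 == counted)
    swap <- match(a1, pool$alleles[[j]]) > match(a2, pool$alleles[[j]])
    pairs[, j] <- ifelse(swap, paste0(a2, "/", a1), paste0(a1, "/", a2))
  }
  list(h1 = h1, h2 = h2, dosage = dosage, pairs = pairs)
}

#' Sample fixed case/control counts from a source population
#'
#' Disease labels are Bernoulli draws from the per-subject probability;
#' the requested numbers of cases and controls are then sampled without
#' replacement from the realized groups (case-control sampling, which
#' preserves odds ratios).
#'
#' @param prob per-subject disease probability.
#' @param n_cases,n_controls requested counts.
#' @return list: `case_idx`, `control_idx`, `labels` (full population
#'   0/1 labels). Errors if the population cannot supply the counts.
#' @export
assign_case_status <- function(prob, n_cases, n_controls) {
  stopifnot(all(prob >= 0 & prob <= 1))
  y <- stats::rbinom(length(prob), 1, prob)
  if (sum(y == 1) < n_cases || sum(y == 0) < n_controls) {
    stop("population too small for requested case/control counts ",
         "(", sum(y == 1), " cases, ", sum(y == 0), " controls realized)")
  }
  list(case_idx = sample(which(y == 1), n_cases),
       control_idx = sample(which(y == 0), n_controls),
       labels = y)
}

#' Set genotypes missing completely at random
#'
#' @param geno dosage matrix (or allele-pair character matrix).
#' @param rates per-SNP missingness rates: single number or named
#'   vector over columns; each in \[0, 1).
#' @param sentinel value used for missing entries (`NA` for dosage
#'   matrices, `"./."` for allele-pair matrices).
#' @return matrix with missing entries set.
#' @export
inject_missingness <- function(geno, rates, sentinel = NA) {
  if (length(rates) == 1L && is.null(names(rates))) {
    rates <- stats::setNames(rep(rates, ncol(geno)), colnames(geno))
  }
  stopifnot(all(rates >= 0 & rates < 1))
  for (snp in colnames(geno)) {
    r <- rates[snp]
    if (is.na(r) || r == 0) next
    hit <- stats::runif(nrow(geno)) < r
    geno[hit, snp] <- sentinel
  }
  geno
}

#' Default configuration for the two-study synthetic cohort
#'
#' Study A emulates a matched nested case-control design (562 cases,
#' 1,553 controls; matching emulated as covariate adjustment), study B
#' a frequency-matched population-based design (1,821 cases, 1,870
#' controls). Disease-model defaults put interaction log-ORs on the two
#' VDR 3' SNPs whose stratum-specific associations motivate the
#' stratified analysis (low-stratum ORs near 0.95, high-stratum near
#' 1.35), a protective rs7041 main effect, and 5% missingness (7% for
#' rs7975232 in study A).
#'
#' @param seed mandatory RNG seed.
#' @return nested list understood by [simulate_study()] /
#'   [simulate_cohort()].
#' @export
default_sim_config <- function(seed) {
  stopifnot(!missing(seed))
  shared <- list(
    vdr_pool = default_vdr_pool(),
    gc_pool = default_gc_pool(),
    gwas_raf = c(rs2228570 = 0.40, rs11568820 = 0.20, rs10741657 = 0.60,
                 rs3829251 = 0.28, rs6013897 = 0.21),
    snp_defs = default_snp_defs(),
    beta_snp = c(rs7041 = log(0.92), rs731236 = log(0.95),
                 rs7975232 = log(0.97)),
    beta_inter = c(rs731236 = log(1.40), rs7975232 = log(1.40)),
    beta_score = 0,
    intercept = stats::qlogis(0.30)
  )
  list(
    seed = seed,
    studies = list(
      studyA = c(shared, list(
        label = "studyA", design = "matched-nested",
        n_cases = 562, n_controls = 1553,
        missing_rates = c(rs7975232 = 0.07), missing_default = 0.05,
        uvb_probs = c("<113" = 0.5, "113" = 0.25, ">113" = 0.25),
        n_plasma = 570)),
      studyB = c(shared, list(
        label = "studyB", design = "frequency-matched",
        n_cases = 1821, n_controls = 1870,
        missing_rates = c(rs2228570 = 0.06), missing_default = 0.05,
        uvb_probs = c("<113" = 1, "113" = 0, ">113" = 0),
        n_plasma = 0))
    )
  )
}

# Draw lifestyle covariates for `n` population members of one study.
.draw_covariates <- function(n, cfg) {
  age <- pmin(pmax(round(stats::rnorm(n, 55, 8)), 30), 79)
  menopause <- ifelse(stats::runif(n) < stats::plogis((age - 51) / 2),
                      "post", "pre")
  draw_month <- sample.int(12, n, replace = TRUE)
  data.frame(
    age = age,
    menopause = menopause,
    bmi = round(stats::rlnorm(n, log(25), 0.18), 1),
    activity = round(stats::rgamma(n, 2, scale = 6), 1),
    diet_vitd = round(stats::rgamma(n, 4, scale = 50)),
    supp_vitd = ifelse(stats::runif(n) < 0.45, 0,
                       sample(c(100, 200, 400, 600), n, replace = TRUE)),
    alcohol = round(ifelse(stats::runif(n) < 0.30, 0,
                           stats::rgamma(n, 1, scale = 8)), 1),
    race = sample(c("white", "black", "hispanic", "asian", "other"), n,
                  replace = TRUE,
                  prob = c(0.94, 0.02, 0.02, 0.01, 0.01)),
    ht_use = ifelse(menopause == "post",
                    sample(c("never", "past", "current", "unknown"), n,
                           replace = TRUE, prob = c(0.30, 0.30, 0.35, 0.05)),
                    NA_character_),
    draw_month = draw_month,
    season = month_to_season(draw_month),
    uvb = sample(names(cfg$uvb_probs), n, replace = TRUE,
                 prob = cfg$uvb_probs),
    stringsAsFactors = FALSE
  )
}

# Population score and high/low indicator (menopause-specific medians).
.population_score <- function(cov) {
  score <- rep(NA_real_, nrow(cov))
  for (st in c("pre", "post")) {
    sel <- cov$menopause == st
    if (!any(sel)) next
    model <- default_score_model(st)
    cats <- categorize(cov[sel, , drop = FALSE], model)
    score[sel] <- predicted_25ohd(cats, model)
  }
  high <- rep(NA_real_, length(score))
  for (st in c("pre", "post")) {
    sel <- cov$menopause == st
    high[sel] <- as.numeric(score[sel] > stats::median(score[sel]))
  }
  list(score = score, high = high)
}

#' Simulate one case-control study
#'
#' Generates a source population (covariates, diplotypes at the VDR 3'
#' and GC loci, independent GWAS SNPs in HWE), applies the logistic
#' disease model `logit P = intercept + sum(beta_g * dosage) +
#' beta_s * high + sum(beta_gs * dosage * high)` where `high` indicates
#' an above-median predicted 25(OH)D score, samples the requested case
#' and control counts, and injects genotype missingness.
#'
#' Caller is responsible for seeding the RNG (see [simulate_cohort()]).
#'
#' @param cfg one study entry of [default_sim_config()].
#' @return list of class `simulated_study`: `subjects` (covariates,
#'   status, true score/stratum), `geno` (risk-allele dosage matrix),
#'   `pairs` (allele-pair strings, `"./."` missing), `snp_defs`,
#'   `truth` (generator parameters).
#' @export
simulate_study <- function(cfg) {
  n_need <- cfg$n_cases + cfg$n_controls
  pop_n <- ceiling(2.6 * n_need)
  for (attempt in 1:5) {
    cov <- .draw_covariates(pop_n, cfg)
    vdr <- draw_diplotypes(cfg$vdr_pool, pop_n)
    gc <- draw_diplotypes(cfg$gc_pool, pop_n)
    gwas <- sapply(names(cfg$gwas_raf), function(s) {
      stats::rbinom(pop_n, 2, cfg$gwas_raf[s])
    })
    # dosage columns count the alphabetically-later allele; convert to
    # risk-allele counts using the declared risk alleles
    geno <- cbind(vdr$dosage, gc$dosage, gwas)
    defs <- cfg$snp_defs
    for (j in seq_len(nrow(defs))) {
      snp <- defs$snp_id[j]
      if (!snp %in% colnames(geno)) next
      if (snp %in% names(cfg$gwas_raf)) next  # already risk-coded
      pool <- if (snp %in% cfg$vdr_pool$snp_ids) cfg$vdr_pool else
        cfg$gc_pool
      counted <- pool$alleles[[match(snp, pool$snp_ids)]][2]
      if (counted != defs$risk_allele[j]) {
        geno[, snp] <- 2L - geno[, snp]
      }
    }
    sc <- .population_score(cov)
    lp <- rep(cfg$intercept, pop_n) + cfg$beta_score * sc$high
    for (s in names(cfg$beta_snp)) {
      lp <- lp + cfg$beta_snp[s] * geno[, s]
    }
    for (s in names(cfg$beta_inter)) {
      lp <- lp + cfg$beta_inter[s] * geno[, s] * sc$high
    }
    draw <- tryCatch(
      assign_case_status(expit(lp), cfg$n_cases, cfg$n_controls),
      error = function(e) NULL)
    if (!is.null(draw)) break
    if (attempt == 5) stop("requested case count unreachable: ",
                           "degenerate disease model intercept")
    pop_n <- pop_n * 2
  }
  idx <- c(draw$case_idx, draw$control_idx)
  status <- rep(c(1L, 0L), c(cfg$n_cases, cfg$n_controls))
  subjects <- cbind(
    data.frame(subject_id = sprintf("%s_%05d", cfg$label, seq_along(idx)),
               study = cfg$label, status = status,
               stringsAsFactors = FALSE),
    cov[idx, , drop = FALSE]
  )
  rownames(subjects) <- NULL
  geno <- geno[idx, , drop = FALSE]
  rownames(geno) <- subjects$subject_id
  pairs <- cbind(vdr$pairs, gc$pairs)[idx, , drop = FALSE]
  # allele-pair strings for the independent GWAS SNPs (risk-coded dosage)
  defs <- cfg$snp_defs
  gwas_pairs <- sapply(names(cfg$gwas_raf), function(s) {
    ra <- defs$risk_allele[defs$snp_id == s]
    oa <- defs$other_allele[defs$snp_id == s]
    het <- paste(csort(c(ra, oa)), collapse = "/")
    c(paste0(oa, "/", oa), het, paste0(ra, "/", ra))[geno[, s] + 1L]
  })
  pairs <- cbind(pairs, gwas_pairs)
  rates <- stats::setNames(
    rep(cfg$missing_default, ncol(geno)), colnames(geno))
  rates[names(cfg$missing_rates)] <- cfg$missing_rates
  geno <- inject_missingness(geno, rates)
  # keep allele-pair strings consistent with the dosage missingness
  pairs[is.na(geno[, colnames(pairs)])] <- "./."
  rownames(pairs) <- subjects$subject_id
  # optional measured plasma 25(OH)D on a subset (study A style)
  subjects$plasma_25ohd <- NA_real_
  if (cfg$n_plasma > 0) {
    sel <- sample.int(nrow(subjects), min(cfg$n_plasma, nrow(subjects)))
    g7041 <- geno[sel, "rs7041"]
    g7041[is.na(g7041)] <- mean(g7041, na.rm = TRUE)
    subjects$plasma_25ohd[sel] <- round(
      40 + 0.8 * (sc$score[idx][sel] - 25) - 2.5 * g7041 +
        stats::rnorm(length(sel), 0, 8), 1)
  }
  structure(list(
    subjects = subjects, geno = geno, pairs = pairs,
    snp_defs = cfg$snp_defs,
    truth = list(score = sc$score[idx], high = sc$high[idx],
                 beta_snp = cfg$beta_snp, beta_inter = cfg$beta_inter,
                 beta_score = cfg$beta_score, intercept = cfg$intercept,
                 sampling = "population oversampling + fixed-count draw")
  ), class = "simulated_study")
}

#' Simulate the full two-study cohort
#'
#' Seeds the RNG from `config$seed` (fixed seed gives byte-identical
#' output) and simulates each configured study.
#'
#' @param config from [default_sim_config()].
#' @return list of class `simulated_cohort`: `subjects` (row-bound),
#'   `geno`, `pairs`, `snp_defs`, `studies` (per-study truth).
#' @export
simulate_cohort <- function(config) {
  stopifnot(!is.null(config$seed))
  set.seed(config$seed)
  sims <- lapply(config$studies, simulate_study)
  structure(list(
    subjects = do.call(rbind, c(lapply(sims, `[[`, "subjects"),
                                list(make.row.names = FALSE))),
    geno = do.call(rbind, lapply(sims, `[[`, "geno")),
    pairs = do.call(rbind, lapply(sims, `[[`, "pairs")),
    snp_defs = sims[[1]]$snp_defs,
    studies = lapply(sims, `[[`, "truth")
  ), class = "simulated_cohort")
}
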