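test_that("haplotype pools validate their invariants", {
  expect_error(haplotype_pool(c("a", "b"), character(0), numeric(0)),
               "empty")
  expect_error(haplotype_pool(c("a", "b"), c("A-B", "A-B"), c(0.5, 0.5)),
               "distinct")
  expect_error(haplotype_pool(c("a", "b"), c("A-B", "a-b"), c(0.6, 0.6)),
               "summing to 1")
  expect_error(haplotype_pool("a", c("A-B", "a-b"), c(0.5, 0.5)),
               "length differs")
  p <- default_vdr_pool()
  expect_equal(sum(p$frequencies), 1, tolerance = 1e-14)
  expect_equal(length(p$haplotypes), 8L)
})

test_that("diplotype draws respect HWE pairing and pool marginals", {
  set.seed(3)
  # degenerate single-haplotype pool: everyone homozygous everywhere
  mono <- haplotype_pool(c("a", "b"), "A-B", 1)
  d0 <- draw_diplotypes(mono, 3)
  expect_true(all(d0$dosage == 2))
  expect_true(all(d0$pairs == matrix(c("A/A", "B/B"), 3, 2, byrow = TRUE)))

  # two-haplotype pool: double-heterozygote proportion is 2 * 0.5 * 0.5
  pool <- haplotype_pool(c("a", "b"), c("A-B", "a-b"), c(0.5, 0.5))
  n <- 10000
  d <- draw_diplotypes(pool, n)
  p_het <- mean(d$dosage[, 1] == 1 & d$dosage[, 2] == 1)
  expect_lt(abs(p_het - 0.5), 3 * sqrt(0.25 / n))

  # per-SNP allele frequencies equal the marginal sums over haplotypes
  vdr <- default_vdr_pool()
  dv <- draw_diplotypes(vdr, n)
  for (j in seq_along(vdr$snp_ids)) {
    counted <- vdr$alleles[[j]][2]
    marginal <- sum(vdr$frequencies[vdr$hap_mat[, j] == counted])
    est <- mean(dv$dosage[, j]) / 2
    expect_lt(abs(est - marginal),
              3 * sqrt(marginal * (1 - marginal) / (2 * n)))
  }
})

test_that("simulated r2 recovers the value implied by pool haplotype frequencies", {
  set.seed(5)
  pool <- default_vdr_pool()
  n <- 10000
  d <- draw_diplotypes(pool, n)
  j1 <- 1; j2 <- 2
  c1 <- pool$alleles[[j1]][2]; c2 <- pool$alleles[[j2]][2]
  p1 <- sum(pool$frequencies[pool$hap_mat[, j1] == c1])
  p2 <- sum(pool$frequencies[pool$hap_mat[, j2] == c2])
  f12 <- sum(pool$frequencies[pool$hap_mat[, j1] == c1 &
                                pool$hap_mat[, j2] == c2])
  implied <- (f12 - p1 * p2)^2 / (p1 * (1 - p1) * p2 * (1 - p2))
  est <- ld_r2(d$dosage, pool$snp_ids[j1], pool$snp_ids[j2])
  expect_lt(abs(est - implied), 0.02)
})

test_that("case assignment retrieves a log-OR of ln(2) for a binary exposure", {
  set.seed(7)
  n <- 20000
  expo <- rbinom(n, 1, 0.4)
  prob <- expit(-1 + log(2) * expo)
  draw <- assign_case_status(prob, 3000, 8000)
  status <- c(rep(1, 3000), rep(0, 8000))
  x <- expo[c(draw$case_idx, draw$control_idx)]
  t <- table(x, status)
  or <- (t["1", "1"] * t["0", "0"]) / (t["0", "1"] * t["1", "0"])
  expect_lt(abs(log(or) - log(2)), 0.12)

  # all-null model: case probability one half
  p0 <- expit(rep(0, 5000))
  d0 <- assign_case_status(p0, 100, 100)
  expect_lt(abs(mean(d0$labels) - 0.5), 3 * sqrt(0.25 / 5000))

  # unreachable counts error out
  expect_error(assign_case_status(rep(1e-6, 100), 90, 10),
               "too small")
})

test_that("interaction coefficient produces stratum-specific odds ratios", {
  set.seed(9)
  n <- 50000
  dose <- rbinom(n, 2, 0.4)
  high <- rbinom(n, 1, 0.5)
  prob <- expit(-1 + log(1.4) * dose * high)   # beta_g = 0
  y <- rbinom(n, 1, prob)
  for (h in 0:1) {
    sel <- high == h
    fit <- glm(y[sel] ~ dose[sel], family = binomial())
    target <- if (h == 1) log(1.4) else 0
    expect_lt(abs(coef(fit)[2] - target), 0.08)
  }
})

test_that("missingness injection hits the requested rates", {
  set.seed(11)
  g <- matrix(1L, 10000, 1, dimnames = list(NULL, "s"))
  expect_identical(inject_missingness(g, 0), g)
  gm <- inject_missingness(g, 0.07)
  expect_lt(abs(sum(is.na(gm)) - 700), 3 * sqrt(10000 * 0.07 * 0.93))

  # fraction of subjects failing >= 5 of 15 SNPs matches binomial tail
  g15 <- matrix(1L, 4000, 15,
                dimnames = list(NULL, paste0("s", 1:15)))
  gm15 <- inject_missingness(g15, 0.05)
  frac <- mean(rowSums(is.na(gm15)) >= 5)
  tail_p <- pbinom(4, 15, 0.05, lower.tail = FALSE)
  expect_lt(abs(frac - tail_p), 3 * sqrt(tail_p * (1 - tail_p) / 4000) +
              1e-4)
})

test_that("fixed seed gives byte-identical cohorts; controls recover pool marginals", {
  cfg <- small_sim_config(123)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  c2 <- simulate_cohort(small_sim_config(124))
  expect_false(identical(a$geno, c2$geno))

  # control risk-allele frequencies track the generator's marginals
  big <- default_sim_config(77)
  big$studies$studyB <- NULL
  big$studies$studyA$n_cases <- 500
  big$studies$studyA$n_controls <- 4000
  co <- simulate_cohort(big)
  ctrl <- co$subjects$status == 0
  defs <- co$snp_defs
  vdr <- big$studies$studyA$vdr_pool
  for (j in seq_along(vdr$snp_ids)) {
    snp <- vdr$snp_ids[j]
    risk <- defs$risk_allele[defs$snp_id == snp]
    marg <- sum(vdr$frequencies[vdr$hap_mat[, j] == risk])
    est <- risk_allele_freq(co$geno, snp, ctrl)
    # controls under-represent risk alleles only slightly (effects modest)
    expect_lt(abs(est - marg), 3 * sqrt(marg * (1 - marg) / (2 * 4000)) +
                0.01)
  }
  g <- big$studies$studyA$gwas_raf
  for (snp in names(g)) {
    est <- risk_allele_freq(co$geno, snp, ctrl)
    expect_lt(abs(est - g[snp]), 3 * sqrt(g[snp] * (1 - g[snp]) / 8000) +
                0.01)
  }
})

test_that("per-allele trend test holds its size on null synthetic genotypes", {
  set.seed(15)
  n_rep <- 1000
  rej <- 0L
  for (i in seq_len(n_rep)) {
    dose <- rbinom(400, 2, 0.3)
    status <- rbinom(400, 1, 0.4)
    if (logistic_trend(status, dose)$p < 0.05) rej <- rej + 1L
  }
  band <- 0.05 + c(-1, 1) * 2.576 * sqrt(0.05 * 0.95 / n_rep)
  expect_gte(rej / n_rep, band[1])
  expect_lte(rej / n_rep, band[2])
})
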