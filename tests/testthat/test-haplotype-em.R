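two_snp_alleles <- list(c("a", "A"), c("b", "B"))

test_that("phase-unambiguous data converge immediately to observed proportions", {
  # all subjects homozygous at every SNP: no ambiguity
  g <- rbind(c(2, 2), c(2, 2), c(0, 0), c(0, 0), c(2, 2), c(0, 0))
  colnames(g) <- c("s1", "s2")
  fit <- em_fit(g, two_snp_alleles, n_restarts = 0)
  f <- setNames(fit$freq, fit$haplotypes)
  expect_equal(unname(f["A-B"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(f["a-b"]), 0.5, tolerance = 1e-12)
  expect_true(fit$converged)
  expect_lte(fit$iterations, 2L)
})

test_that("double-heterozygote likelihood surface: symmetric start stays, skewed start resolves", {
  # every subject doubly heterozygous: coupling and repulsion are
  # indistinguishable from a symmetric start, which is a stationary point
  g <- matrix(1, 10, 2, dimnames = list(NULL, c("s1", "s2")))
  prep <- vitdgxe:::.em_prepare(g, two_snp_alleles)
  sym <- vitdgxe:::.em_run(prep, rep(0.25, 4), tol = 1e-10, max_iter = 500)
  expect_equal(sym$freq, rep(0.25, 4), tolerance = 1e-9)
  # a coupling-leaning start converges to the coupling-phase solution
  skew <- vitdgxe:::.em_run(prep, c(0.45, 0.05, 0.05, 0.45),
                            tol = 1e-10, max_iter = 2000)
  f <- setNames(skew$freq, prep$labels)
  expect_equal(unname(f["a-b"] + f["A-B"]), 1, tolerance = 1e-6)
  expect_gte(skew$loglik, sym$loglik)
})

test_that("EM recovers simulated haplotype frequencies within 0.01 at n = 5000", {
  set.seed(31)
  pool <- default_vdr_pool()
  d <- draw_diplotypes(pool, 5000)
  fit <- em_fit(d$dosage, pool$alleles, seed = 2)
  expect_true(fit$converged)
  est <- setNames(fit$freq, fit$haplotypes)[pool$haplotypes]
  expect_true(all(abs(est - pool$frequencies) < 0.01))
  # frequencies sum to one; log-likelihood trace is non-decreasing
  expect_equal(sum(fit$freq), 1, tolerance = 1e-10)
  expect_true(all(diff(fit$trace) > -1e-8))
})

test_that("EM log-likelihood attains the simplex grid-search maximum", {
  set.seed(41)
  # 2-SNP locus, mixed ambiguous/unambiguous subjects
  pool <- haplotype_pool(c("s1", "s2"), c("A-B", "a-b", "A-b"),
                         c(0.5, 0.4, 0.1))
  d <- draw_diplotypes(pool, 10)
  fit <- em_fit(d$dosage, pool$alleles, seed = 3)
  gmax <- grid_loglik_max(d$dosage)
  expect_gte(fit$loglik, gmax - 1e-4)

  # 3-SNP locus with the third SNP homozygous throughout (support 4)
  g3 <- cbind(d$dosage[1:8, ], s3 = rep(2L, 8))
  fit3 <- em_fit(g3, c(pool$alleles, list(c("c", "C"))), seed = 3)
  gmax3 <- grid_loglik_max(g3)
  expect_gte(fit3$loglik, gmax3 - 1e-4)
})

test_that("estimates are invariant to subject order and SNP column order", {
  set.seed(51)
  pool <- default_vdr_pool()
  d <- draw_diplotypes(pool, 600)
  fit <- em_fit(d$dosage, pool$alleles, seed = 2)
  perm <- sample(nrow(d$dosage))
  fit_rows <- em_fit(d$dosage[perm, ], pool$alleles, seed = 2)
  expect_equal(setNames(fit_rows$freq, fit_rows$haplotypes),
               setNames(fit$freq, fit$haplotypes), tolerance = 1e-6)
  # reverse SNP order: same frequencies up to haplotype relabeling
  rev_idx <- ncol(d$dosage):1
  fit_cols <- em_fit(d$dosage[, rev_idx], pool$alleles[rev_idx], seed = 2)
  relabel <- sapply(strsplit(fit_cols$haplotypes, "-"),
                    function(x) paste(rev(x), collapse = "-"))
  expect_equal(setNames(fit_cols$freq, relabel)[fit$haplotypes],
               setNames(fit$freq, fit$haplotypes), tolerance = 1e-6)
})

test_that("expected dosages: unambiguous, balanced, and skewed posteriors", {
  # homozygous subject: dosage 2 on its single haplotype
  g <- rbind(c(2, 2), c(1, 1))
  colnames(g) <- c("s1", "s2")
  model <- em_fit(rbind(c(2, 2), c(0, 0), c(2, 2), c(0, 0)),
                  two_snp_alleles, n_restarts = 0)
  dt <- expected_dosages(model, g[1, , drop = FALSE])
  expect_equal(unname(dt$dosage[1, "A-B"]), 2, tolerance = 1e-12)

  # double het under f(AB) = f(ab) = 0.5: dosage 1 on each coupling hap
  dt2 <- expected_dosages(model, g)
  expect_equal(unname(dt2$dosage[2, "A-B"]), 1, tolerance = 1e-9)
  expect_equal(unname(dt2$dosage[2, "a-b"]), 1, tolerance = 1e-9)

  # hand-computed two-term posterior under f = (0.4, 0.1, 0.1, 0.4):
  # P(coupling) = 0.32/0.34 = 16/17
  skew <- model
  skew$freq <- c(0.4, 0.1, 0.1, 0.4)[match(model$haplotypes,
                                           c("a-b", "A-b", "a-B", "A-B"))]
  dt3 <- expected_dosages(skew, g)
  expect_equal(unname(dt3$dosage[2, "A-B"]), 16 / 17, tolerance = 1e-9)
  expect_equal(unname(dt3$dosage[2, "a-B"]), 1 / 17, tolerance = 1e-9)

  # fully missing subjects are excluded, not zero-filled
  gmiss <- rbind(c(2, 2), c(NA, NA))
  rownames(gmiss) <- c("kept", "dropped")
  colnames(gmiss) <- c("s1", "s2")
  dt4 <- expected_dosages(model, gmiss)
  expect_equal(rownames(dt4$dosage), "kept")
  expect_equal(dt4$excluded, "dropped")
})

test_that("dosages sum to 2 and column means match frequencies", {
  set.seed(61)
  pool <- default_vdr_pool()
  d <- draw_diplotypes(pool, 1500)
  fit <- em_fit(d$dosage, pool$alleles, seed = 2)
  dt <- expected_dosages(fit, d$dosage)
  expect_true(all(abs(rowSums(dt$dosage) - 2) < 1e-8))
  # no missing genotypes here: mean dosage / 2 equals frequency estimate
  expect_equal(unname(colMeans(dt$dosage) / 2), unname(dt$freq),
               tolerance = 1e-6)
  # still conserved with missing genotypes
  gm <- inject_missingness(d$dosage, 0.1)
  dtm <- expected_dosages(fit, gm)
  expect_true(all(abs(rowSums(dtm$dosage) - 2) < 1e-8))
})

test_that("rare haplotype grouping pools sub-threshold columns", {
  set.seed(71)
  pool <- default_vdr_pool()
  d <- draw_diplotypes(pool, 3000)
  fit <- em_fit(d$dosage, pool$alleles, seed = 2)
  dt <- expected_dosages(fit, d$dosage)
  grouped <- group_rare(dt)
  # three common haplotypes + one pooled rare column
  expect_setequal(colnames(grouped$dosage),
                  c("G-C-T", "A-A-C", "G-A-T", "rare"))
  expect_true(all(abs(rowSums(grouped$dosage) - 2) < 1e-8))
  expect_equal(sum(grouped$freq), 1, tolerance = 1e-9)

  # two-haplotype table is unchanged at the default threshold
  pool2 <- haplotype_pool(c("x", "y"), c("A-B", "a-b"), c(0.5, 0.5))
  d2 <- draw_diplotypes(pool2, 200)
  dt2 <- expected_dosages(em_fit(d2$dosage, two_snp_alleles, seed = 1),
                          d2$dosage)
  expect_identical(colnames(group_rare(dt2)$dosage), colnames(dt2$dosage))

  # all-rare grouping is refused
  fake <- dt2
  fake$freq[] <- 0.04
  expect_error(group_rare(fake), "no reference haplotype")
})

test_that("GC phenotype assignment follows the isoform map and Ka ladder", {
  set.seed(81)
  pool <- default_gc_pool()
  d <- draw_diplotypes(pool, 500)
  fit <- em_fit(d$dosage, pool$alleles, seed = 2)
  dt <- expected_dosages(fit, d$dosage)
  # forced examples: T/T+T/T, G/G+G/G, G/G+G/T
  g <- rbind(c(2, 2), c(0, 0), c(0, 1))
  colnames(g) <- c("rs4588", "rs7041")
  ph <- gc_phenotype(expected_dosages(fit, g))
  expect_equal(ph$phenotype, c("GC2-GC2", "GC1s-GC1s", "GC1s-GC1f"))
  expect_equal(ph$ka, c(3.6, 6.0, 8.6))

  # cohort-level: all phenotypes drawn from the six-level ladder
  all_ph <- gc_phenotype(dt)
  expect_true(all(all_ph$ka %in% c(3.6, 4.8, 6.0, 7.4, 8.6, 11.2)))

  # a prominent non-isoform haplotype (T-G) raises the coding alarm
  bad_pool <- haplotype_pool(c("rs4588", "rs7041"),
                             c("G-G", "T-T", "T-G"), c(0.5, 0.3, 0.2))
  db <- draw_diplotypes(bad_pool, 400)
  fb <- em_fit(db$dosage, bad_pool$alleles, seed = 2)
  expect_warning(gc_phenotype(expected_dosages(fb, db$dosage)),
                 "check allele coding")
})
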