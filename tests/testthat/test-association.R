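test_that("covariate-free logistic OR equals the 2x2 cross-product ratio", {
  d <- expand_2x2(matrix(c(80, 70, 20, 30), 2, byrow = TRUE))
  # cases 30 exposed / 70 not; controls 20 / 80
  fit <- logistic_trend(d$status, d$expo)
  expect_equal(fit$or, (30 * 80) / (70 * 20), tolerance = 1e-6)
  expect_equal(fit$or, 1.714, tolerance = 1e-3)
  expect_equal(fit$n_cases, 100L)
  expect_equal(fit$n_controls, 100L)

  set.seed(13)
  for (i in 1:50) {
    t <- random_2x2()
    d <- expand_2x2(t)
    fit <- logistic_trend(d$status, d$expo)
    cross <- (t[2, 2] * t[1, 1]) / (t[1, 2] * t[2, 1])
    expect_equal(fit$or, cross, tolerance = 1e-6)
  }
})

test_that("logistic trend rejects degenerate inputs and flags separation", {
  expect_error(logistic_trend(c(0, 0, 1, 1), rep(1, 4)),
               "no variation")
  expect_error(logistic_trend(rep(1, 4), c(0, 1, 0, 1)),
               "at least one case and one control")
  # perfect separation -> flagged row, not silent NaN
  sep <- suppressWarnings(
    logistic_trend(c(rep(0, 20), rep(1, 20)),
                   c(rep(0, 20), rep(1, 20))))
  expect_equal(sep$error, "separation")
  expect_true(is.na(sep$or))
})

test_that("allele recoding reflects the OR to its reciprocal", {
  set.seed(17)
  status <- rbinom(500, 1, 0.4)
  dose <- rbinom(500, 2, 0.3)
  a <- logistic_trend(status, dose)
  b <- logistic_trend(status, 2 - dose)
  expect_equal(b$or, 1 / a$or, tolerance = 1e-8)
  expect_equal(b$ci_low, 1 / a$ci_high, tolerance = 1e-8)
})

test_that("per-allele estimator covers a simulated OR of 1.38", {
  set.seed(19)
  beta <- log(1.38)
  hits <- 0L
  n_rep <- 400
  for (i in seq_len(n_rep)) {
    dose <- rbinom(2000, 2, 0.35)
    status <- rbinom(2000, 1, expit(-0.6 + beta * dose))
    fit <- logistic_trend(status, dose)
    ci <- log(c(fit$ci_low, fit$ci_high))
    if (beta >= ci[1] && beta <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.925)
})

test_that("two-haplotype regression collapses to the single-dosage trend", {
  set.seed(23)
  pool <- haplotype_pool(c("x", "y"), c("A-B", "a-b"), c(0.6, 0.4))
  d <- draw_diplotypes(pool, 800)
  fit <- em_fit(d$dosage, pool$alleles, seed = 1)
  dt <- expected_dosages(fit, d$dosage)
  status <- rbinom(800, 1, expit(-0.3 + 0.4 * dt$dosage[, "a-b"]))
  hap <- haplotype_regression(status, dt)
  trend <- logistic_trend(status, dt$dosage[, "a-b"])
  expect_equal(hap$term, "a-b")  # reference is the most common (A-B)
  expect_equal(hap$estimate, trend$estimate, tolerance = 1e-8)
  expect_equal(hap$se, trend$se, tolerance = 1e-8)

  # all subjects homozygous for the reference: nothing to estimate
  mono <- dt
  mono$dosage <- matrix(rep(c(2, 0), each = 800), 800, 2,
                        dimnames = list(NULL, c("A-B", "a-b")))
  expect_error(haplotype_regression(status, mono), "no variation")
})

test_that("per-haplotype Wald test holds its size under the null", {
  set.seed(29)
  pool <- default_vdr_pool()
  n_rep <- 300
  rej <- 0L
  for (i in seq_len(n_rep)) {
    d <- draw_diplotypes(pool, 400)
    dt <- expected_dosages(em_fit(d$dosage, pool$alleles, n_restarts = 0),
                           d$dosage)
    g <- group_rare(dt)
    status <- rbinom(400, 1, 0.45)    # independent of genotype
    rows <- haplotype_regression(status, g)
    # test the non-reference member of the two common haplotypes
    tt <- intersect(c("A-A-C", "G-C-T"), rows$term)[1]
    if (rows$p[rows$term == tt] < 0.05) rej <- rej + 1L
  }
  # 99% binomial band around 0.05 at 300 replicates
  band <- 0.05 + c(-1, 1) * 2.576 * sqrt(0.05 * 0.95 / n_rep)
  expect_gte(rej / n_rep, band[1])
  expect_lte(rej / n_rep, band[2])
})

test_that("GC trend uses the printed Ka ladder and needs 2+ levels", {
  set.seed(31)
  pool <- default_gc_pool()
  d <- draw_diplotypes(pool, 1200)
  fit <- em_fit(d$dosage, pool$alleles, seed = 1)
  dt <- expected_dosages(fit, d$dosage)
  ph <- gc_phenotype(dt)
  # monotone effect over Ka is detected
  status <- rbinom(1200, 1, expit(-2 + 0.25 * ph$ka))
  res <- gc_trend(status, ph)
  expect_lt(res$trend$p, 0.01)
  expect_gt(res$trend$estimate, 0)
  expect_true(all(res$indicators$term %in%
                    c("GC2-GC1s", "GC1s-GC1s", "GC2-GC1f",
                      "GC1s-GC1f", "GC1f-GC1f")))
  # single-level phenotype is refused
  ph1 <- ph
  ph1$phenotype <- "GC2-GC2"
  ph1$ka <- 3.6
  expect_error(gc_trend(status, ph1), "fewer than 2")
})

test_that("linear biomarker model recovers effects and detects collinearity", {
  set.seed(37)
  n <- 600
  g <- rbinom(n, 2, 0.4)
  grs_val <- g + rbinom(n, 6, 0.3)
  y <- 40 - 2 * grs_val + rnorm(n, 0, 6)
  fit <- linear_biomarker(y, grs_val)
  expect_lt(abs(fit$estimate - (-2)), 3 * fit$se)
  expect_equal(fit$scale, "linear")

  # null exposure: size ~ 5% over replicates
  rej <- 0L
  for (i in 1:200) {
    yy <- rnorm(200)
    xx <- rbinom(200, 2, 0.5)
    if (linear_biomarker(yy, xx)$p < 0.05) rej <- rej + 1L
  }
  expect_lt(abs(rej / 200 - 0.05), 0.05)

  # confounded season shifts the estimate unless adjusted
  season <- rbinom(n, 1, 0.5)
  x2 <- g + 2 * season
  y2 <- 10 * season + rnorm(n)
  raw <- linear_biomarker(y2, x2)
  adj <- linear_biomarker(y2, x2, data.frame(season = season))
  expect_gt(abs(raw$estimate), abs(adj$estimate) + 0.5)

  expect_error(linear_biomarker(y[1:5], g[1:5]), "fewer than 10")
  expect_error(
    linear_biomarker(y, g, data.frame(dup = g)),
    "collinear")
})

test_that("haplotype interaction LRT: df counting and degenerate stratum", {
  set.seed(41)
  n <- 500
  dos <- cbind(h1 = rbinom(n, 2, 0.3), h2 = rbinom(n, 2, 0.2),
               h3 = rbinom(n, 2, 0.1))
  status <- rbinom(n, 1, 0.4)
  stratum <- sample(c("low", "high"), n, replace = TRUE)
  res <- haplotype_interaction_lrt(status, dos, stratum)
  expect_equal(res$df, 3L)
  expect_gte(res$lrt, 0)
  # constant stratum: products vanish, LRT = 0
  res0 <- haplotype_interaction_lrt(status, dos, rep("low", n))
  expect_equal(res0$lrt, 0, tolerance = 1e-6)
})

test_that("haplotype interaction LRT p-values are uniform under the null", {
  set.seed(43)
  n_rep <- 200
  ps <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    n <- 300
    dos <- cbind(h1 = rbinom(n, 2, 0.35), h2 = rbinom(n, 2, 0.25))
    stratum <- sample(c("low", "high"), n, replace = TRUE)
    status <- rbinom(n, 1, expit(-0.2 + 0.2 * dos[, 1]))
    ps[i] <- haplotype_interaction_lrt(status, dos, stratum)$p
  }
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
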