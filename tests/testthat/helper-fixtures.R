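# Shared fixture builders and independent oracles.

# Independent HWE chi-square oracle: trinomial expected counts computed
# from scratch (kept separate from hwe_test()).
oracle_hwe <- function(n2, n1, n0) {
  n <- n2 + n1 + n0
  p <- (2 * n2 + n1) / (2 * n)
  e <- c(p * p * n, 2 * p * (1 - p) * n, (1 - p) * (1 - p) * n)
  o <- c(n2, n1, n0)
  sum((o - e)^2 / e)
}

# Exhaustive-likelihood oracle for small haplotype problems: grid
# search over the frequency simplex (step 0.01) restricted to the
# haplotypes compatible with the observed genotypes.
grid_loglik_max <- function(genotypes, step = 0.01) {
  m <- ncol(genotypes)
  bits <- as.matrix(expand.grid(rep(list(0:1), m)))
  # subject-wise compatible ordered pairs
  subj_pairs <- lapply(seq_len(nrow(genotypes)), function(r) {
    g <- genotypes[r, ]
    ok <- which(vapply(seq_len(nrow(bits)), function(i) {
      all(is.na(g) | bits[i, ] <= g) && all(is.na(g) | bits[i, ] >= g - 1)
    }, logical(1)))
    pairs <- expand.grid(i = ok, j = ok)
    keep <- vapply(seq_len(nrow(pairs)), function(k) {
      s <- bits[pairs$i[k], ] + bits[pairs$j[k], ]
      all(is.na(g) | s == g)
    }, logical(1))
    as.matrix(pairs[keep, , drop = FALSE])
  })
  support <- sort(unique(unlist(lapply(subj_pairs, as.vector))))
  k <- length(support)
  stopifnot(k <= 4)  # grid over larger supports is not attempted
  steps <- round(1 / step)
  combos <- expand.grid(rep(list(0:steps), k - 1))
  combos <- combos[rowSums(combos) <= steps, , drop = FALSE]
  grid <- cbind(as.matrix(combos), steps - rowSums(combos)) * step
  ll <- numeric(nrow(grid))
  for (sp in subj_pairs) {
    ii <- match(sp[, "i"], support)
    jj <- match(sp[, "j"], support)
    lik <- rowSums(grid[, ii, drop = FALSE] * grid[, jj, drop = FALSE])
    ll <- ll + log(lik)
  }
  max(ll[is.finite(ll)])
}

# Brute-force BH oracle: does the step-up rule reject each hypothesis
# at level q?  (epsilon guards float round-trip at exact thresholds)
bh_reject <- function(p, q) {
  m <- length(p)
  s <- sort(p)
  k <- which(s <= q * seq_len(m) / m + 1e-12)
  if (!length(k)) return(rep(FALSE, m))
  p <= s[max(k)]
}

# smallest attainable level at which each p is rejected
bh_brute_adjust <- function(p) {
  m <- length(p)
  qs <- sort(unique(c(1, pmin(1, m * sort(p) / seq_len(m)))))
  vapply(seq_along(p), function(j) {
    hit <- vapply(qs, function(q) bh_reject(p, q)[j], logical(1))
    qs[which(hit)[1]]
  }, numeric(1))
}

# Random 2x2 case-control table with all cells positive.
random_2x2 <- function() {
  repeat {
    t <- matrix(sample(5:80, 4, replace = TRUE), 2)
    if (all(t > 0)) return(t)
  }
}

# Expand a 2x2 (exposure x status) table to subject-level vectors.
expand_2x2 <- function(t) {
  # rows: unexposed/exposed; cols: control/case
  status <- rep(c(0, 1, 0, 1), c(t[1, 1], t[1, 2], t[2, 1], t[2, 2]))
  expo <- rep(c(0, 0, 1, 1), c(t[1, 1], t[1, 2], t[2, 1], t[2, 2]))
  list(status = status, expo = expo)
}

# Small simulation config used across pipeline tests.
small_sim_config <- function(seed, n_cases = 250, n_controls = 350) {
  cfg <- default_sim_config(seed)
  for (s in names(cfg$studies)) {
    cfg$studies[[s]]$n_cases <- n_cases
    cfg$studies[[s]]$n_controls <- n_controls
  }
  cfg
}
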