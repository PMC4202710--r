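# Haplotype frequency estimation from unphased genotypes.
#
# Loci are small (<= 8 SNPs), so the 2^m haplotype space and each
# subject's phase-consistent diplotypes are enumerated exhaustively.
# Subjects with partially missing genotypes contribute by summing over
# all compatible haplotype completions inside the E-step.

# Enumerate compatible (h1 <= h2) haplotype-index pairs for one genotype
# pattern. `g` is a length-m vector of 0/1/2/NA counts of allele "1";
# `bits` the H x m haplotype allele matrix.
.compatible_pairs <- function(g, bits) {
  typed <- which(!is.na(g))
  h_ok <- rep(TRUE, nrow(bits))
  for (j in typed) {
    h_ok <- h_ok & if (g[j] == 0) bits[, j] == 0 else
      if (g[j] == 2) bits[, j] == 1 else TRUE
  }
  cand <- which(h_ok)
  out_i <- integer(0); out_j <- integer(0)
  for (i in cand) {
    # partner alleles are forced at typed SNPs, free at missing ones
    p_ok <- rep(TRUE, nrow(bits))
    for (j in typed) p_ok <- p_ok & bits[, j] == g[j] - bits[i, j]
    partners <- which(p_ok)
    partners <- partners[partners >= i]
    out_i <- c(out_i, rep.int(i, length(partners)))
    out_j <- c(out_j, partners)
  }
  cbind(i = out_i, j = out_j, mult = ifelse(out_i == out_j, 1, 2))
}

# Shared pre-processing: haplotype space, per-pattern compatibility.
.em_prepare <- function(genotypes, alleles) {
  m <- ncol(genotypes)
  stopifnot(m >= 1, m <= 8)
  if (is.null(alleles)) {
    alleles <- rep(list(c("0", "1")), m)
  }
  stopifnot(length(alleles) == m)
  bits <- as.matrix(expand.grid(rep(list(0:1), m))[, m:1, drop = FALSE])
  dimnames(bits) <- NULL
  labels <- apply(bits, 1, function(b) {
    paste(mapply(function(a, x) a[x + 1], alleles, b), collapse = "-")
  })
  all_missing <- rowSums(!is.na(genotypes)) == 0
  if (all(all_missing)) stop("all subjects fully missing at this locus")
  used <- genotypes[!all_missing, , drop = FALSE]
  key <- apply(used, 1, paste, collapse = ",")
  patterns <- !duplicated(key)
  pat_geno <- used[patterns, , drop = FALSE]
  pat_n <- as.vector(table(key)[key[patterns]])
  pairs <- lapply(seq_len(nrow(pat_geno)), function(r) {
    .compatible_pairs(pat_geno[r, ], bits)
  })
  list(bits = bits, labels = labels, used = used,
       pat_n = pat_n, pairs = pairs,
       subject_pattern = match(key, key[patterns]),
       dropped = rownames(genotypes)[all_missing], alleles = alleles)
}

# One EM run from a given initial frequency vector.
.em_run <- function(prep, f, tol, max_iter) {
  n2 <- 2 * sum(prep$pat_n)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    counts <- numeric(length(f))
    ll <- 0
    for (p in seq_along(prep$pairs)) {
      pr <- prep$pairs[[p]]
      lik <- f[pr[, "i"]] * f[pr[, "j"]] * pr[, "mult"]
      s <- sum(lik)
      if (s <= 0) return(list(freq = f, loglik = -Inf, trace = trace,
                              iterations = iter, converged = FALSE))
      post <- prep$pat_n[p] * lik / s
      same <- pr[, "i"] == pr[, "j"]
      for (r in seq_len(nrow(pr))) {
        counts[pr[r, "i"]] <- counts[pr[r, "i"]] + post[r] * (if (same[r]) 2 else 1)
        if (!same[r]) counts[pr[r, "j"]] <- counts[pr[r, "j"]] + post[r]
      }
      ll <- ll + prep$pat_n[p] * log(s)
    }
    trace <- c(trace, ll)
    f_new <- counts / n2
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  list(freq = f, loglik = trace[length(trace)], trace = trace,
       iterations = iter, converged = converged)
}

#' Fit haplotype frequencies by expectation-maximization
#'
#' Estimates multi-SNP haplotype frequencies from unphased genotype
#' dosages. The E-step computes posterior probabilities of every
#' phase-consistent diplotype under current frequencies (summing over
#' compatible completions for subjects with missing SNPs); the M-step
#' sets each frequency to the average expected haplotype count divided
#' by two. Iteration stops when the largest absolute frequency change
#' falls below `tol`.
#'
#' The default start is the linkage-equilibrium product of observed
#' single-SNP allele frequencies; `n_restarts` additional random starts
#' (fixed sub-seeds derived from `seed`) guard against local maxima such
#' as the symmetric double-heterozygote stationary point, and the run
#' with the best final log-likelihood is kept.
#'
#' @param genotypes subjects x SNPs matrix of 0/1/2 allele counts
#'   (`NA` = missing); at most 8 SNPs.
#' @param alleles optional list (one element per SNP) of the two allele
#'   labels, `c(allele0, allele1)` where the genotype counts allele1;
#'   used to label haplotypes like `"G-C-T"`.
#' @param tol convergence tolerance on frequencies (default 1e-8).
#' @param max_iter maximum EM iterations (default 1000).
#' @param n_restarts number of extra random initializations (default 5).
#' @param seed seed for the random restarts.
#' @return object of class `haplotype_model`: `snp_ids`, `haplotypes`
#'   (labels for all 2^m haplotypes), `hap_bits`, `freq`, `loglik`,
#'   `trace` (per-iteration log-likelihood of the winning run),
#'   `iterations`, `converged`, `n_used`, `dropped`.
#' @export
em_fit <- function(genotypes, alleles = NULL, tol = 1e-8, max_iter = 1000,
                   n_restarts = 5, seed = 1L) {
  genotypes <- as.matrix(genotypes)
  if (is.null(rownames(genotypes))) {
    rownames(genotypes) <- paste0("s", seq_len(nrow(genotypes)))
  }
  prep <- .em_prepare(genotypes, alleles)
  H <- nrow(prep$bits)
  # linkage-equilibrium start from observed allele frequencies
  afreq <- colMeans(prep$used, na.rm = TRUE) / 2
  afreq <- pmin(pmax(afreq, 1e-6), 1 - 1e-6)
  f_le <- apply(prep$bits, 1, function(b) {
    prod(ifelse(b == 1, afreq, 1 - afreq))
  })
  inits <- list(f_le / sum(f_le))
  if (n_restarts > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    for (r in seq_len(n_restarts)) {
      g <- stats::rgamma(H, shape = 1)
      inits[[r + 1L]] <- g / sum(g)
    }
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }
  best <- NULL
  for (f0 in inits) {
    run <- .em_run(prep, f0, tol, max_iter)
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }
  if (!best$converged) {
    warning("EM did not converge within ", max_iter, " iterations")
  }
  structure(list(
    snp_ids = colnames(genotypes) %||% paste0("snp", seq_len(ncol(genotypes))),
    alleles = prep$alleles,
    haplotypes = prep$labels,
    hap_bits = prep$bits,
    freq = best$freq,
    loglik = best$loglik,
    trace = best$trace,
    iterations = best$iterations,
    converged = best$converged,
    n_used = nrow(prep$used),
    dropped = prep$dropped
  ), class = "haplotype_model")
}

#' @export
print.haplotype_model <- function(x, ...) {
  cat(sprintf("EM haplotype model: %d SNPs, %d subjects, logLik %.4f (%s)\n",
              length(x$snp_ids), x$n_used, x$loglik,
              if (x$converged) "converged" else "NOT converged"))
  keep <- x$freq > 1e-6
  print(round(stats::setNames(x$freq[keep], x$haplotypes[keep]), 4))
  invisible(x)
}

#' Expected haplotype dosages per subject
#'
#' Posterior-weighted counts (0-2) of each haplotype carried by each
#' subject under a fitted model, the "expectation substitution" scores
#' used as additive covariates in haplotype regression. The most
#' probable diplotype and its posterior probability are recorded per
#' subject. Subjects missing every SNP at the locus are excluded (never
#' zero-filled).
#'
#' @param model a `haplotype_model` from [em_fit()].
#' @param genotypes genotype matrix as in [em_fit()].
#' @param require_converged error if the model did not converge.
#' @return object of class `dosage_table`: `dosage` (subjects x
#'   haplotypes, columns restricted to haplotypes with positive
#'   estimated frequency), `freq`, `best` (most-probable diplotype and
#'   posterior per subject), `excluded`.
#' @export
expected_dosages <- function(model, genotypes, require_converged = TRUE) {
  stopifnot(inherits(model, "haplotype_model"))
  if (require_converged && !model$converged) {
    stop("model did not converge; pass require_converged = FALSE to override")
  }
  genotypes <- as.matrix(genotypes)
  if (is.null(rownames(genotypes))) {
    rownames(genotypes) <- paste0("s", seq_len(nrow(genotypes)))
  }
  prep <- .em_prepare(genotypes, model$alleles)
  f <- model$freq
  n_used <- nrow(prep$used)
  H <- length(f)
  dos <- matrix(0, n_used, H)
  best_d <- character(n_used)
  best_p <- numeric(n_used)
  for (p in seq_along(prep$pairs)) {
    pr <- prep$pairs[[p]]
    lik <- f[pr[, "i"]] * f[pr[, "j"]] * pr[, "mult"]
    s <- sum(lik)
    if (s <= 0) stop("genotype pattern with zero likelihood under model")
    post <- lik / s
    d <- numeric(H)
    for (r in seq_len(nrow(pr))) {
      d[pr[r, "i"]] <- d[pr[r, "i"]] + post[r]
      d[pr[r, "j"]] <- d[pr[r, "j"]] + post[r]
    }
    top <- which.max(post)
    lab <- paste(csort(model$haplotypes[c(pr[top, "i"], pr[top, "j"])]),
                 collapse = "/")
    rows <- which(prep$subject_pattern == p)
    dos[rows, ] <- matrix(d, length(rows), H, byrow = TRUE)
    best_d[rows] <- lab
    best_p[rows] <- post[top]
  }
  keep <- f > 1e-9
  dosage <- dos[, keep, drop = FALSE]
  colnames(dosage) <- model$haplotypes[keep]
  rownames(dosage) <- rownames(prep$used)
  structure(list(
    dosage = dosage,
    freq = stats::setNames(f[keep], model$haplotypes[keep]),
    best = data.frame(subject_id = rownames(prep$used),
                      diplotype = best_d, posterior = best_p,
                      stringsAsFactors = FALSE),
    excluded = prep$dropped
  ), class = "dosage_table")
}

#' Pool rare haplotypes into a single dosage column
#'
#' Haplotypes with estimated frequency below `threshold` (default 5%)
#' are summed into one `"rare"` column; per-subject dosages still sum
#' to 2.
#'
#' @param dosages a `dosage_table` from [expected_dosages()].
#' @param threshold grouping frequency in (0, 0.5).
#' @return a `dosage_table` with grouped columns.
#' @export
group_rare <- function(dosages, threshold = 0.05) {
  stopifnot(inherits(dosages, "dosage_table"),
            threshold > 0, threshold < 0.5)
  rare <- dosages$freq < threshold
  if (all(rare)) stop("no reference haplotype: all haplotypes rare")
  if (!any(rare)) return(dosages)
  kept <- dosages$dosage[, !rare, drop = FALSE]
  out <- cbind(kept, rare = rowSums(dosages$dosage[, rare, drop = FALSE]))
  freq <- c(dosages$freq[!rare], rare = sum(dosages$freq[rare]))
  structure(list(dosage = out, freq = freq, best = dosages$best,
                 excluded = dosages$excluded,
                 grouped = names(dosages$freq)[rare]),
            class = "dosage_table")
}

# Binding-affinity constants (Ka x 1e-10 / M) of the six GC isoform
# diplotypes, used as the trend variable over GC phenotypes.
GC_KA <- c("GC2-GC2" = 3.6, "GC2-GC1s" = 4.8, "GC1s-GC1s" = 6.0,
           "GC2-GC1f" = 7.4, "GC1s-GC1f" = 8.6, "GC1f-GC1f" = 11.2)

#' Derive GC (vitamin D binding protein) phenotypes
#'
#' The two GC coding SNPs (rs4588, rs7041, in that order) define three
#' protein isoforms via haplotypes: T-T = GC2, G-G = GC1s, G-T = GC1f.
#' Each subject is assigned the isoform pair of their most probable
#' diplotype, with the corresponding 25(OH)D binding-affinity constant
#' from the six-level ladder (GC2-GC2 3.6 ... GC1f-GC1f 11.2). Subjects
#' whose most probable diplotype involves the non-isoform T-G haplotype
#' get a missing phenotype; a T-G estimated frequency above
#' `alarm_freq` triggers a warning since it usually signals an
#' allele-coding error.
#'
#' @param dosages a `dosage_table` fitted on the two GC SNPs.
#' @param iso_map named map from haplotype label to isoform.
#' @param alarm_freq warning threshold for non-isoform haplotype
#'   frequency (default 0.01).
#' @return data.frame with `subject_id`, `phenotype` (e.g. "GC1s-GC1f"),
#'   `ka`; attribute `n_nonisoform` counts subjects set missing.
#' @export
gc_phenotype <- function(dosages,
                         iso_map = c("T-T" = "GC2", "G-G" = "GC1s",
                                     "G-T" = "GC1f"),
                         alarm_freq = 0.01) {
  stopifnot(inherits(dosages, "dosage_table"))
  noniso <- setdiff(names(dosages$freq), names(iso_map))
  bad <- dosages$freq[noniso]
  if (length(bad) && any(bad > alarm_freq)) {
    warning("non-isoform haplotype frequency ",
            paste0(names(bad[bad > alarm_freq]), "=",
                   signif(bad[bad > alarm_freq], 3), collapse = ", "),
            " exceeds ", alarm_freq, "; check allele coding")
  }
  rank <- c(GC2 = 1L, GC1s = 2L, GC1f = 3L)
  parts <- strsplit(dosages$best$diplotype, "/", fixed = TRUE)
  pheno <- vapply(parts, function(hp) {
    iso <- iso_map[hp]
    if (any(is.na(iso))) return(NA_character_)
    paste(iso[order(rank[iso])], collapse = "-")
  }, character(1))
  out <- data.frame(subject_id = dosages$best$subject_id,
                    phenotype = pheno,
                    ka = unname(GC_KA[pheno]),
                    stringsAsFactors = FALSE)
  attr(out, "n_nonisoform") <- sum(is.na(pheno))
  out
}
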