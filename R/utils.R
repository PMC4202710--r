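# z for 95% CIs; more digits than 1.96 so printed CIs round-trip cleanly
Z95 <- 1.959964

expit <- function(x) 1 / (1 + exp(-x))

# locale-independent (C collation) character sort, so allele and
# haplotype orderings do not depend on LC_COLLATE
csort <- function(x) sort(x, method = "radix")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate.
#' @param m number of tests.
#' @return `alpha / m`.
#' @examples
#' bonferroni(0.05, 54)
#' @export
bonferroni <- function(alpha, m) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha <= 1)
  if (!is.numeric(m) || length(m) != 1L || m < 1) {
    stop("'m' must be a positive number of tests")
  }
  alpha / m
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment. Thin wrapper over
#' [stats::p.adjust()] kept so multiplicity handling has a single,
#' tested entry point in this package.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order as input.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) stop("empty p-value vector")
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must be in [0, 1] and non-missing")
  }
  stats::p.adjust(p, method = "BH")
}
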