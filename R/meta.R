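#' Recover the log-OR standard error from a printed OR and 95% CI
#'
#' Published per-study rows report an odds ratio and its 95% confidence
#' interval; pooling them requires the log-odds-ratio and its standard
#' error. Under a Wald interval, `SE = (ln(hi) - ln(lo)) / (2 * 1.959964)`.
#'
#' A warning is issued when the printed point estimate deviates from the
#' geometric mid-point of the interval by more than 2%, which usually
#' indicates a transcription error or a non-Wald interval.
#'
#' @param or_point odds ratio point estimate.
#' @param ci_low,ci_high 95% confidence limits.
#' @return standard error of the log odds ratio.
#' @examples
#' se_from_ci(1.17, 1.02, 1.36)
#' @export
se_from_ci <- function(or_point, ci_low, ci_high) {
  if (any(c(or_point, ci_low, ci_high) <= 0)) {
    stop("odds ratio and confidence limits must be positive")
  }
  if (any(ci_low > or_point) || any(or_point > ci_high)) {
    stop("require ci_low <= or_point <= ci_high")
  }
  mid <- exp((log(ci_low) + log(ci_high)) / 2)
  bad <- abs(mid - or_point) / or_point > 0.02
  if (any(bad)) {
    warning("CI not log-symmetric around the point estimate (>2% deviation)")
  }
  (log(ci_high) - log(ci_low)) / (2 * Z95)
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Pools study-level log odds ratios with the method-of-moments
#' between-study variance. With fixed weights `w_i = 1/s_i^2`, the
#' fixed-effect pool is `theta_F = sum(w theta)/sum(w)`, Cochran's
#' `Q = sum(w (theta - theta_F)^2)`, and
#' `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))`.
#' Random-effects weights `1/(s_i^2 + tau2)` give the pooled estimate,
#' its standard error, and a 95% CI on the odds-ratio scale. The
#' heterogeneity p-value is the upper chi-square tail of Q at `k - 1`
#' degrees of freedom.
#'
#' With a single study the input is returned unchanged (`Q` and `p_het`
#' are not applicable and reported as `NA`).
#'
#' @param theta study log odds ratios.
#' @param se their standard errors (all positive).
#' @param labels optional study labels.
#' @return object of class `meta_result`: list with `theta`, `se`, `or`,
#'   `ci_low`, `ci_high`, `tau2`, `q`, `df`, `p_het`, `k`, and the inputs.
#' @examples
#' dl_meta(log(c(1.17, 1.07)),
#'         c(se_from_ci(1.17, 1.02, 1.36), se_from_ci(1.07, 0.92, 1.25)))
#' @export
dl_meta <- function(theta, se, labels = NULL) {
  k <- length(theta)
  if (k == 0L) stop("no studies to pool")
  if (length(se) != k) stop("'theta' and 'se' lengths differ")
  if (any(!is.finite(theta)) || any(!is.finite(se)) || any(se <= 0)) {
    stop("all estimates must be finite and all SEs > 0")
  }
  if (k == 1L) {
    pooled <- theta
    pse <- se
    q <- NA_real_
    tau2 <- 0
    p_het <- NA_real_
  } else {
    w <- 1 / se^2
    theta_f <- sum(w * theta) / sum(w)
    q <- sum(w * (theta - theta_f)^2)
    tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
    w_star <- 1 / (se^2 + tau2)
    pooled <- sum(w_star * theta) / sum(w_star)
    pse <- 1 / sqrt(sum(w_star))
    p_het <- stats::pchisq(q, df = k - 1, lower.tail = FALSE)
  }
  structure(list(
    theta = pooled, se = pse,
    or = exp(pooled),
    ci_low = exp(pooled - Z95 * pse),
    ci_high = exp(pooled + Z95 * pse),
    tau2 = tau2, q = q, df = if (k > 1L) k - 1L else NA_integer_,
    p_het = p_het, k = k,
    input = data.frame(
      label = labels %||% paste0("study", seq_len(k)),
      theta = theta, se = se
    )
  ), class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("DerSimonian-Laird meta-analysis of %d estimate(s)\n", x$k))
  cat(sprintf("  pooled OR %.2f (95%% CI %.2f-%.2f)\n",
              x$or, x$ci_low, x$ci_high))
  if (x$k > 1L) {
    cat(sprintf("  Q = %.3f (df %d), p_het = %.3g, tau2 = %.4g\n",
                x$q, x$df, x$p_het, x$tau2))
  }
  invisible(x)
}

#' Cochran Q heterogeneity between two stratum estimates
#'
#' Tests whether a genetic association differs between exposure strata
#' (e.g., low vs high predicted 25(OH)D) by comparing the two stratum
#' log odds ratios with fixed inverse-variance weights.
#'
#' @param theta_low,se_low log-OR and SE in the low stratum.
#' @param theta_high,se_high log-OR and SE in the high stratum.
#' @return list with `q`, `df` (1), and `p_het`; all `NA` when either
#'   stratum estimate is missing.
#' @export
strata_heterogeneity <- function(theta_low, se_low, theta_high, se_high) {
  if (any(is.na(c(theta_low, se_low, theta_high, se_high)))) {
    return(list(q = NA_real_, df = 1L, p_het = NA_real_))
  }
  m <- dl_meta(c(theta_low, theta_high), c(se_low, se_high),
               labels = c("low", "high"))
  list(q = m$q, df = 1L, p_het = m$p_het)
}
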