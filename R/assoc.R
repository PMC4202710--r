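# Regression layer: every model returns standardized effect-estimate
# rows so the reporting and meta stages can treat SNPs, haplotypes, GC
# phenotypes, and the GRS uniformly.

.effect_row <- function(term, study = "", stratum = "all",
                        estimate = NA_real_, se = NA_real_,
                        p = NA_real_, n_cases = NA_integer_,
                        n_controls = NA_integer_, scale = "logor",
                        error = NA_character_) {
  data.frame(
    term = term, study = study, stratum = stratum,
    estimate = estimate, se = se,
    or = if (scale == "logor") exp(estimate) else NA_real_,
    ci_low = if (scale == "logor") exp(estimate - Z95 * se) else
      estimate - Z95 * se,
    ci_high = if (scale == "logor") exp(estimate + Z95 * se) else
      estimate + Z95 * se,
    p = p, n_cases = n_cases, n_controls = n_controls,
    scale = scale, error = error, stringsAsFactors = FALSE
  )
}

# Complete-case design assembly shared by the fitters.
.complete_design <- function(outcome, exposure, covariates) {
  df <- data.frame(.y = outcome)
  if (is.matrix(exposure) || is.data.frame(exposure)) {
    df <- cbind(df, as.data.frame(exposure))
    expo_names <- colnames(exposure)
  } else {
    df$.x <- exposure
    expo_names <- ".x"
  }
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == length(outcome))
    df <- cbind(df, covariates)
  }
  keep <- stats::complete.cases(df)
  list(df = df[keep, , drop = FALSE], expo = expo_names, kept = keep)
}

.fit_logistic <- function(df) {
  stats::glm(.y ~ ., data = df, family = stats::binomial(),
             control = stats::glm.control(epsilon = 1e-10, maxit = 100))
}

# divergence of the Wald estimate signals (quasi-)separation
.separated <- function(fit) {
  !fit$converged || any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE)
}

#' Per-allele logistic trend model
#'
#' Unconditional logistic regression of case status on a 0/1/2 (or
#' continuous expected) risk-allele dosage plus adjustment covariates;
#' the per-allele odds ratio is `exp(beta)` with a two-sided Wald trend
#' p-value. Complete-case analysis; the numbers of cases and controls
#' actually used are recorded.
#'
#' @param outcome binary case status (0/1).
#' @param dosage exposure dosage (0/1/2 or real).
#' @param covariates optional data.frame of adjustment covariates.
#' @param term,study,stratum labels carried into the output row.
#' @return one-row effect-estimate data.frame. Separation or
#'   non-convergence yields a flagged row (`error` code), never a
#'   silent `NaN`.
#' @export
logistic_trend <- function(outcome, dosage, covariates = NULL,
                           term = "dosage", study = "", stratum = "all") {
  stopifnot(all(outcome %in% c(0, 1) | is.na(outcome)))
  d <- .complete_design(outcome, dosage, covariates)
  df <- d$df
  if (nrow(df) == 0 || length(unique(df$.y)) < 2) {
    stop("need at least one case and one control")
  }
  if (length(unique(df$.x)) < 2) stop("exposure has no variation")
  fit <- .fit_logistic(df)
  n_ca <- sum(df$.y == 1)
  n_co <- sum(df$.y == 0)
  if (.separated(fit)) {
    return(.effect_row(term, study, stratum, n_cases = n_ca,
                       n_controls = n_co, error = "separation"))
  }
  sm <- summary(fit)$coefficients
  .effect_row(term, study, stratum,
              estimate = sm[".x", "Estimate"],
              se = sm[".x", "Std. Error"],
              p = sm[".x", "Pr(>|z|)"],
              n_cases = n_ca, n_controls = n_co)
}

#' Haplotype dosage regression
#'
#' One logistic model containing an expected-dosage covariate for every
#' non-reference haplotype (additive inheritance); the reference is the
#' most common haplotype and is omitted from the design. Returns one
#' effect row per non-reference haplotype.
#'
#' @param outcome binary case status aligned with `dosages$dosage` rows.
#' @param dosages a `dosage_table` (typically after [group_rare()]).
#' @param covariates optional adjustment data.frame (aligned rows).
#' @param reference reference haplotype; default the highest-frequency
#'   haplotype, ties broken lexicographically.
#' @param study,stratum labels for the output rows.
#' @return effect-estimate data.frame, one row per non-reference
#'   haplotype.
#' @export
haplotype_regression <- function(outcome, dosages, covariates = NULL,
                                 reference = NULL, study = "",
                                 stratum = "all") {
  stopifnot(inherits(dosages, "dosage_table"))
  mat <- dosages$dosage
  if (is.null(reference)) {
    top <- max(dosages$freq)
    reference <- csort(names(dosages$freq)[dosages$freq == top])[1]
  }
  others <- setdiff(colnames(mat), reference)
  keep_col <- others[apply(mat[, others, drop = FALSE], 2,
                           function(x) length(unique(x)) > 1)]
  if (!length(keep_col)) stop("no variation in any non-reference haplotype")
  if (length(keep_col) < length(others)) {
    warning("dropping empty haplotype column(s): ",
            paste(setdiff(others, keep_col), collapse = ", "))
  }
  x <- mat[, keep_col, drop = FALSE]
  colnames(x) <- make.names(colnames(x))
  d <- .complete_design(outcome, x, covariates)
  df <- d$df
  fit <- .fit_logistic(df)
  n_ca <- sum(df$.y == 1); n_co <- sum(df$.y == 0)
  if (.separated(fit)) {
    return(.effect_row(keep_col, study, stratum, n_cases = n_ca,
                       n_controls = n_co, error = "separation"))
  }
  sm <- summary(fit)$coefficients
  do.call(rbind, lapply(seq_along(keep_col), function(i) {
    cf <- make.names(keep_col[i])
    .effect_row(keep_col[i], study, stratum,
                estimate = sm[cf, "Estimate"], se = sm[cf, "Std. Error"],
                p = sm[cf, "Pr(>|z|)"], n_cases = n_ca, n_controls = n_co)
  }))
}

#' GC phenotype association: indicator and binding-affinity trend models
#'
#' (a) An indicator logistic model of case status on GC phenotype with
#' GC2-GC2 as reference, one OR per phenotype; and (b) a trend model
#' using the phenotype's 25(OH)D binding-affinity constant Ka as a
#' continuous covariate, giving a single Wald trend p.
#'
#' @param outcome binary case status.
#' @param phenotype data.frame from [gc_phenotype()] (rows aligned).
#' @param covariates optional adjustment data.frame.
#' @param study,stratum labels.
#' @return list with `indicators` (effect rows vs GC2-GC2) and `trend`
#'   (one row, estimate per Ka unit).
#' @export
gc_trend <- function(outcome, phenotype, covariates = NULL,
                     study = "", stratum = "all") {
  lev <- names(GC_KA)
  ph <- factor(phenotype$phenotype, levels = lev)
  present <- lev[lev %in% ph]
  if (length(present) < 2) stop("fewer than 2 GC phenotype levels present")
  nonref <- lev[-1]
  cols <- make.names(paste0("ph_", nonref))
  ind_full <- matrix(NA_real_, length(ph), length(nonref),
                     dimnames = list(NULL, cols))
  ok <- !is.na(ph)
  for (i in seq_along(nonref)) {
    ind_full[ok, i] <- as.numeric(ph[ok] == nonref[i])
  }
  empty <- colSums(ind_full, na.rm = TRUE) == 0
  d <- .complete_design(outcome, ind_full[, !empty, drop = FALSE],
                        covariates)
  fit <- .fit_logistic(d$df)
  n_ca <- sum(d$df$.y == 1); n_co <- sum(d$df$.y == 0)
  sm <- summary(fit)$coefficients
  indicators <- do.call(rbind, lapply(which(!empty), function(i) {
    .effect_row(nonref[i], study, stratum,
                estimate = sm[cols[i], "Estimate"],
                se = sm[cols[i], "Std. Error"],
                p = sm[cols[i], "Pr(>|z|)"],
                n_cases = n_ca, n_controls = n_co)
  }))
  trend <- logistic_trend(outcome, phenotype$ka, covariates,
                          term = "ka_trend", study = study,
                          stratum = stratum)
  list(indicators = indicators, trend = trend)
}

#' Linear model for plasma 25(OH)D on genotype dosage or GRS
#'
#' Ordinary least squares of the measured biomarker on a per-allele
#' dosage or genetic risk score, adjusted for the usual covariates
#' (age, study, race, season of blood draw).
#'
#' @param outcome continuous plasma 25(OH)D.
#' @param exposure dosage or GRS.
#' @param covariates optional adjustment data.frame.
#' @param term,study labels.
#' @return one-row effect-estimate data.frame on the linear scale
#'   (beta per allele / per GRS unit).
#' @export
linear_biomarker <- function(outcome, exposure, covariates = NULL,
                             term = "dosage", study = "") {
  d <- .complete_design(outcome, exposure, covariates)
  df <- d$df
  if (nrow(df) < 10) stop("fewer than 10 complete cases")
  fit <- stats::lm(.y ~ ., data = df)
  if (fit$rank < ncol(stats::model.matrix(fit))) {
    bad <- names(which(is.na(stats::coef(fit))))
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  .effect_row(term, study, stratum = "all",
              estimate = sm[".x", "Estimate"], se = sm[".x", "Std. Error"],
              p = sm[".x", "Pr(>|t|)"],
              n_cases = NA_integer_, n_controls = NA_integer_,
              scale = "linear")
}

#' Wald cross-product test for genotype-by-stratum interaction
#'
#' Logistic model with dosage, stratum indicator, their product, and
#' covariates; the reported p is the two-sided Wald test of the product
#' coefficient. Subjects with missing stratum are excluded.
#'
#' @param outcome binary case status.
#' @param dosage risk-allele dosage.
#' @param stratum character/factor with levels low/high ("missing"
#'   excluded).
#' @param covariates optional adjustment data.frame.
#' @param study label.
#' @return list: `term`, `study`, `wald_z`, `p`, `estimate` (log-OR of
#'   the product term), `se`, `n`.
#' @export
interaction_wald <- function(outcome, dosage, stratum, covariates = NULL,
                             study = "") {
  keep <- stratum %in% c("low", "high")
  outcome <- outcome[keep]; dosage <- dosage[keep]
  high <- as.numeric(stratum[keep] == "high")
  if (!is.null(covariates)) covariates <- covariates[keep, , drop = FALSE]
  if (length(unique(high)) < 2) stop("stratum indicator is constant")
  x <- cbind(.x = dosage, .high = high, .xhigh = dosage * high)
  d <- .complete_design(outcome, x, covariates)
  fit <- .fit_logistic(d$df)
  if (.separated(fit)) {
    return(list(term = "dosage:high", study = study, wald_z = NA_real_,
                p = NA_real_, estimate = NA_real_, se = NA_real_,
                n = nrow(d$df), error = "separation"))
  }
  sm <- summary(fit)$coefficients
  list(term = "dosage:high", study = study,
       wald_z = sm[".xhigh", "z value"], p = sm[".xhigh", "Pr(>|z|)"],
       estimate = sm[".xhigh", "Estimate"], se = sm[".xhigh", "Std. Error"],
       n = nrow(d$df), error = NA_character_)
}

#' Global likelihood-ratio test for haplotype-by-stratum interaction
#'
#' Pooled individual-level data from both studies: the full logistic
#' model has haplotype dosages, stratum, covariates (study, score), and
#' one product term per non-reference haplotype; the reduced model
#' drops the products. `LRT = 2 * (llik_full - llik_reduced)` on as
#' many degrees of freedom as product terms.
#'
#' @param outcome binary case status.
#' @param dosages matrix of non-reference haplotype dosages.
#' @param stratum low/high/missing per subject.
#' @param covariates optional data.frame (should include study and the
#'   continuous predicted score).
#' @return list: `lrt`, `df`, `p`.
#' @export
haplotype_interaction_lrt <- function(outcome, dosages, stratum,
                                      covariates = NULL) {
  dosages <- as.matrix(dosages)
  keep <- stratum %in% c("low", "high")
  outcome <- outcome[keep]
  dosages <- dosages[keep, , drop = FALSE]
  high <- as.numeric(stratum[keep] == "high")
  if (!is.null(covariates)) covariates <- covariates[keep, , drop = FALSE]
  colnames(dosages) <- make.names(colnames(dosages))
  prods <- dosages * high
  colnames(prods) <- paste0(colnames(dosages), ".x.high")
  x_red <- cbind(dosages, .high = high)
  x_full <- cbind(x_red, prods)
  d_full <- .complete_design(outcome, x_full, covariates)
  # reduced model refit on the identical complete-case rows
  fit_full <- .fit_logistic(d_full$df)
  red_df <- d_full$df[, setdiff(colnames(d_full$df), colnames(prods)),
                      drop = FALSE]
  fit_red <- .fit_logistic(red_df)
  lrt <- max(0, 2 * (stats::logLik(fit_full) - stats::logLik(fit_red)))
  df <- ncol(prods)
  list(lrt = as.numeric(lrt), df = df,
       p = stats::pchisq(as.numeric(lrt), df = df, lower.tail = FALSE))
}
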