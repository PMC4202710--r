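# Predicted 25(OH)D score: a covariate-weighted linear surrogate for
# plasma 25-hydroxyvitamin D, built from categorized lifestyle
# predictors with menopause-specific weights, then dichotomized at the
# control median of each (study, menopause) cell.

# A covariate definition is either numeric (breaks + printed labels,
# rounded to `digits` before categorization) or categorical (levels).
.cov_numeric <- function(breaks, labels, digits, weights) {
  stopifnot(length(labels) == length(breaks),
            length(weights) == length(labels))
  list(type = "numeric", breaks = breaks, labels = labels,
       digits = digits, weights = stats::setNames(weights, labels))
}

.cov_categorical <- function(levels, weights) {
  stopifnot(length(weights) == length(levels))
  list(type = "categorical", labels = levels,
       weights = stats::setNames(weights, levels))
}

#' Default predicted 25(OH)D score model
#'
#' Category boundaries follow the published predictor categories: BMI
#' (<22.0, 22.0-24.9, 25.0-29.9, 30-34.9, 35+ kg/m2), physical activity
#' (<3, 3-8.9, 9-17.9, 18-26.9, 27+ METs/week), dietary vitamin D
#' (<100, 100-199, 200-299, 300-399, 400+ IU/day), supplemental vitamin
#' D (0, 1-199, 200-399, 400+ IU/day), alcohol (0, 0.1-4.9, 5-9.9, 10+
#' g/day), race/ethnicity, UV-B flux (<113, 113, >113 R-B units),
#' season of blood draw, hormone-therapy use (postmenopausal stratum
#' only; never/past/current/unknown). The weights themselves are not
#' published, so this ships a plausible default set (vitamin D intake,
#' activity, alcohol, and UV-B increase the score; BMI decreases it);
#' analyses that depend only on the ranking of scores are unaffected by
#' the particular weights.
#'
#' @param stratum `"pre"` or `"post"` menopausal model.
#' @return object of class `score_model`.
#' @export
default_score_model <- function(stratum = c("pre", "post")) {
  stratum <- match.arg(stratum)
  covs <- list(
    race = .cov_categorical(
      c("white", "black", "hispanic", "asian", "other"),
      c(0, -9, -3, -4, -3)),
    bmi = .cov_numeric(
      breaks = c(0, 22, 25, 30, 35),
      labels = c("<22.0", "22.0-24.9", "25.0-29.9", "30-34.9", "35+"),
      digits = 1, weights = c(0, -2, -4, -7, -9)),
    activity = .cov_numeric(
      breaks = c(0, 3, 9, 18, 27),
      labels = c("<3", "3-8.9", "9-17.9", "18-26.9", "27+"),
      digits = 1, weights = c(0, 1, 2, 3, 4)),
    diet_vitd = .cov_numeric(
      breaks = c(0, 100, 200, 300, 400),
      labels = c("<100", "100-199", "200-299", "300-399", "400+"),
      digits = 0, weights = c(0, 1, 2, 3, 4)),
    supp_vitd = .cov_numeric(
      breaks = c(0, 1, 200, 400),
      labels = c("0", "1-199", "200-399", "400+"),
      digits = 0, weights = c(0, 2, 4, 6)),
    alcohol = .cov_numeric(
      breaks = c(0, 0.1, 5, 10),
      labels = c("0", "0.1-4.9", "5-9.9", "10+"),
      digits = 1, weights = c(0, 1, 2, 3)),
    uvb = .cov_categorical(c("<113", "113", ">113"), c(0, 1.5, 3)),
    season = .cov_categorical(c("Winter", "Spring", "Summer", "Fall"),
                              c(0, 1, 6, 4)),
    age = .cov_numeric(
      breaks = c(0, 40, 50, 60, 70),
      labels = c("<40", "40-49", "50-59", "60-69", "70+"),
      digits = 0, weights = c(0, -0.5, -1, -1.5, -2))
  )
  if (stratum == "post") {
    covs$ht_use <- .cov_categorical(c("never", "past", "current", "unknown"),
                                    c(0, 0.5, 1.5, 0.2))
  }
  structure(list(stratum = stratum, intercept = 25, covariates = covs),
            class = "score_model")
}

#' Categorize covariates for the predicted 25(OH)D score
#'
#' Numeric values are rounded to the decimal precision of the printed
#' category labels, then assigned with lower-inclusive boundaries: a
#' category labelled "22.0-24.9" is \[22.0, 25.0). Printed labels like
#' "0 / 0.1-4.9" only partition the axis after this rounding; e.g.
#' alcohol 0.05 g/day rounds to 0.0 and falls in category "0".
#'
#' @param data data.frame of per-subject covariates; column names must
#'   match the model's covariate names.
#' @param model a `score_model`.
#' @return data.frame of category labels (character), `NA` where the
#'   input is missing.
#' @export
categorize <- function(data, model) {
  stopifnot(inherits(model, "score_model"))
  out <- list()
  for (nm in names(model$covariates)) {
    cv <- model$covariates[[nm]]
    if (!nm %in% names(data)) stop("missing covariate column: ", nm)
    x <- data[[nm]]
    if (cv$type == "numeric") {
      if (any(!is.na(x) & x < 0)) {
        stop("negative value for covariate ", nm)
      }
      xr <- round(x, cv$digits)
      idx <- findInterval(xr, cv$breaks)
      if (any(!is.na(idx) & idx == 0)) {
        stop("value below first category for covariate ", nm)
      }
      out[[nm]] <- cv$labels[idx]
    } else {
      bad <- !is.na(x) & !x %in% cv$labels
      if (any(bad)) {
        stop("unmappable level '", x[bad][1], "' for covariate ", nm)
      }
      out[[nm]] <- as.character(x)
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Predicted 25(OH)D score
#'
#' Deterministic linear score: intercept plus the weight of each
#' covariate's category. Any missing required covariate gives a missing
#' score (never treated as zero).
#'
#' @param categories data.frame from [categorize()].
#' @param model a `score_model`.
#' @return numeric vector of scores (arbitrary linear units).
#' @export
predicted_25ohd <- function(categories, model) {
  stopifnot(inherits(model, "score_model"))
  score <- rep(model$intercept, nrow(categories))
  for (nm in names(model$covariates)) {
    w <- model$covariates[[nm]]$weights[categories[[nm]]]
    score <- score + unname(w)
  }
  score
}

#' Dichotomize scores at menopause-specific control medians
#'
#' The cutoff is the median score among controls of the same study and
#' menopause stratum; cases are classified against that control median.
#' Scores strictly above the median are "high", at or below it "low"
#' (ties go low). Subjects with a missing score, or in a cell with no
#' scored controls, are "missing" and excluded from stratified analyses.
#'
#' @param score numeric scores.
#' @param is_control logical, TRUE for controls.
#' @param study study label per subject.
#' @param menopause menopause stratum per subject.
#' @return character vector in `{"low", "high", "missing"}`.
#' @export
dichotomize <- function(score, is_control, study, menopause) {
  n <- length(score)
  stopifnot(length(is_control) == n, length(study) == n,
            length(menopause) == n)
  out <- rep("missing", n)
  cell <- interaction(study, menopause, drop = TRUE)
  for (cl in levels(cell)) {
    in_cell <- cell == cl
    ctrl_scores <- score[in_cell & is_control]
    ctrl_scores <- ctrl_scores[!is.na(ctrl_scores)]
    if (length(ctrl_scores) < 2) {
      warning("no usable control scores in cell ", cl,
              "; subjects set missing")
      next
    }
    med <- stats::median(ctrl_scores)
    ok <- in_cell & !is.na(score)
    out[ok] <- ifelse(score[ok] > med, "high", "low")
  }
  out
}

#' Vitamin D insufficiency genetic risk score
#'
#' Unweighted sum of risk-allele counts over the four independent GWAS
#' loci for plasma 25(OH)D (by default rs4588, rs10741657, rs3829251,
#' rs6013897 -- the GC, CYP2R1, NADSYN1/DHCR7, and CYP24A1 loci).
#'
#' @param geno genotype dosage matrix.
#' @param snp_ids the component SNP columns.
#' @param impute_missing if TRUE, a missing component is replaced by the
#'   mean dosage of that SNP; default FALSE gives a missing GRS.
#' @return numeric vector of GRS values in \[0, 2 * length(snp_ids)\].
#' @export
grs <- function(geno, snp_ids = c("rs4588", "rs10741657", "rs3829251",
                                  "rs6013897"),
                impute_missing = FALSE) {
  miss <- setdiff(snp_ids, colnames(geno))
  if (length(miss)) stop("GRS SNPs absent from matrix: ",
                         paste(miss, collapse = ", "))
  g <- geno[, snp_ids, drop = FALSE]
  if (impute_missing) {
    for (j in seq_len(ncol(g))) {
      g[is.na(g[, j]), j] <- mean(g[, j], na.rm = TRUE)
    }
  }
  rowSums(g)
}
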