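# Plain-text interchange: subject/genotype TSVs, optional VCF 4.2
# export/import, and YAML run configuration.

#' Write subject table and allele-pair genotypes as TSV
#'
#' One row per subject: `subject_id`, `study`, `status`, covariates,
#' then one column per SNP with `"A/C"`-style allele pairs (`"./."`
#' missing).
#'
#' @param subjects subject data.frame.
#' @param pairs allele-pair character matrix (rownames = subject ids).
#' @param path output file.
#' @export
write_cohort_tsv <- function(subjects, pairs, path) {
  stopifnot(all(subjects$subject_id == rownames(pairs)))
  utils::write.table(cbind(subjects, as.data.frame(pairs)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a cohort TSV written by [write_cohort_tsv()]
#'
#' @param path TSV file.
#' @param snp_defs SNP definition data.frame (risk/other alleles) used
#'   to convert allele pairs back to risk-allele dosages; half calls
#'   and `"./."` become `NA`.
#' @return list: `subjects`, `geno` (risk dosage matrix), `pairs`.
#' @export
read_cohort_tsv <- function(path, snp_defs) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  snps <- intersect(snp_defs$snp_id, names(df))
  pairs <- as.matrix(df[snps])
  rownames(pairs) <- df$subject_id
  geno <- matrix(NA_integer_, nrow(df), length(snps),
                 dimnames = list(df$subject_id, snps))
  for (s in snps) {
    ra <- snp_defs$risk_allele[snp_defs$snp_id == s]
    al <- strsplit(pairs[, s], "/", fixed = TRUE)
    geno[, s] <- vapply(al, function(a) {
      if (length(a) != 2 || any(a == ".")) return(NA_integer_)
      sum(a == ra)
    }, integer(1))
  }
  list(subjects = df[setdiff(names(df), snps)], geno = geno,
       pairs = pairs)
}

#' Export genotypes as a minimal VCF 4.2
#'
#' Biallelic SNP records with a GT FORMAT field; missing genotypes are
#' `"./."`. REF is the risk allele's counterpart (other allele), ALT
#' the risk allele, so allele dosage equals the alt count.
#'
#' @param geno risk-allele dosage matrix.
#' @param snp_defs SNP definitions (risk/other alleles).
#' @param path output file.
#' @export
write_vcf <- function(geno, snp_defs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", rownames(geno)),
                     collapse = "\t")), con)
  gt_map <- c("0/0", "0/1", "1/1")
  for (i in seq_len(ncol(geno))) {
    snp <- colnames(geno)[i]
    def <- snp_defs[snp_defs$snp_id == snp, ]
    g <- geno[, i]
    gt <- ifelse(is.na(g), "./.", gt_map[g + 1L])
    writeLines(paste(c("1", i, snp, def$other_allele, def$risk_allele,
                       ".", "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotype dosages from a VCF
#'
#' Parses biallelic SNP records; the GT field is converted to a
#' risk-allele dosage using the declared risk allele of each SNP (alt
#' count if the risk allele is ALT, reference count otherwise). Half
#' calls become missing.
#'
#' @param path VCF file.
#' @param snp_defs SNP definitions.
#' @return risk-allele dosage matrix (subjects x SNPs).
#' @export
read_vcf_genotypes <- function(path, snp_defs) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  out <- matrix(NA_integer_, ncol(gt), nrow(gt),
                dimnames = list(colnames(gt), fix[, "ID"]))
  for (i in seq_len(nrow(gt))) {
    snp <- fix[i, "ID"]
    def <- snp_defs[snp_defs$snp_id == snp, ]
    if (nrow(def) == 0) next
    alt_count <- vapply(strsplit(gt[i, ], "[/|]"), function(a) {
      if (length(a) != 2 || any(a == ".") || any(is.na(a))) {
        return(NA_integer_)
      }
      sum(a == "1")
    }, integer(1))
    risk_is_alt <- def$risk_allele == fix[i, "ALT"]
    out[, snp] <- if (risk_is_alt) alt_count else 2L - alt_count
  }
  out
}

#' Read a YAML run configuration
#'
#' @param path YAML file; must contain a `seed` entry.
#' @return named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config must set a seed")
  cfg
}

#' Published per-study per-allele OR rows for meta-analysis validation
#'
#' Study-level per-allele odds ratios and 95% CIs, as published, for
#' the SNPs whose two-study inputs are available in print. Used by the
#' validation mode of the pipeline: converting each row to a log-OR/SE
#' and pooling must reproduce the published pooled ORs.
#'
#' @param path optional TSV override with columns `label`, `study`,
#'   `or`, `ci_low`, `ci_high`.
#' @return data.frame of printed rows.
#' @export
published_main_effects <- function(path = NULL) {
  path <- path %||% system.file("extdata", "published_main_effects.tsv",
                                package = "vitdgxe", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Published stratum-specific OR rows (low/high predicted 25(OH)D)
#'
#' @param path optional TSV override with columns `label`, `stratum`,
#'   `or`, `ci_low`, `ci_high`, `p_het_printed`.
#' @return data.frame of printed stratum rows.
#' @export
published_stratum_effects <- function(path = NULL) {
  path <- path %||% system.file("extdata", "published_stratum_effects.tsv",
                                package = "vitdgxe", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
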