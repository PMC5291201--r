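#' Variant quality-control filter
#'
#' Retains variants passing the study's genotype filters: Hardy-Weinberg
#' equilibrium p-value strictly above `hwe_min`, minor allele frequency at or
#' below `maf_max`, and imputation info score strictly above `info_min`.
#' Missing info scores (hard-called data) are treated as passing, with a
#' message. Idempotent by construction.
#'
#' @param variants Tibble with columns `maf`, `hwe_p` and optionally
#'   `info_score`.
#' @param hwe_min Hardy-Weinberg lower p-value bound (exclusive).
#' @param maf_max MAF ceiling (inclusive); must lie in (0, 0.5].
#' @param info_min Imputation info floor (exclusive).
#' @return The retained rows of `variants`.
#' @export
filter_variants <- function(variants, hwe_min = 5e-7, maf_max = 0.05,
                            info_min = 0.8) {
  if (!is.numeric(maf_max) || maf_max <= 0 || maf_max > 0.5) {
    abort("`maf_max` must lie in (0, 0.5].")
  }
  variants <- as_tibble(variants)
  if (nrow(variants) == 0) return(variants)
  info <- if ("info_score" %in% names(variants)) variants$info_score else
    rep(NA_real_, nrow(variants))
  if (anyNA(info)) {
    inform("Missing imputation info scores treated as passing (hard-called data).")
    info[is.na(info)] <- 1
  }
  keep <- variants$hwe_p > hwe_min & variants$maf <= maf_max & info > info_min
  variants[keep, , drop = FALSE]
}

#' Rank-based inverse normal transform
#'
#' Maps values to normal quantiles of their (average-tie) ranks using the
#' rankit offset: \eqn{\Phi^{-1}((r_i - c) / (n - 2c + 1))} with `c = 0.5`.
#' Used on methylation values to tame outliers before association testing.
#' Missing values are preserved in place; ranks are computed among the
#' non-missing values only.
#'
#' @param values Numeric vector with at least 3 distinct non-missing values.
#' @param offset Rank offset `c` (default 0.5, the rankit scheme).
#' @return Numeric vector of transformed values, same length as input.
#' @examples
#' rank_inverse_normal(c(5, 1, 9))
#' @export
rank_inverse_normal <- function(values, offset = 0.5) {
  ok <- !is.na(values)
  x <- values[ok]
  if (length(x) < 3) abort("Need at least 3 non-missing values.")
  if (length(unique(x)) == 1) {
    abort("All values identical: rank transform undefined.")
  }
  r <- rank(x, ties.method = "average")
  n <- length(x)
  out <- values
  out[ok] <- qnorm((r - offset) / (n - 2 * offset + 1))
  out
}

#' Residualize a trait on covariates
#'
#' Ordinary least-squares residuals of `y` on an intercept plus the given
#' covariates. Residuals are orthogonal to every design column; applying the
#' operation twice with the same covariates is a no-op (projection
#' idempotence).
#'
#' @inheritParams fit_null
#' @return Numeric residual vector.
#' @export
residualize <- function(y, covariates = NULL) {
  fit_null(y, covariates)$residuals
}

#' Mean-impute missing dosages
#'
#' Replaces missing entries of each variant column with that variant's mean
#' observed dosage. Fails on fully missing variants. MAF should be
#' recomputed afterwards (see [dosage_maf()], which this preserves since the
#' column mean is unchanged).
#'
#' @param dosages Matrix (samples x variants), possibly with `NA` entries.
#' @return Completed matrix of the same shape.
#' @export
impute_missing_dosages <- function(dosages) {
  dosages <- as.matrix(dosages)
  nas <- colSums(is.na(dosages))
  if (any(nas == nrow(dosages))) {
    bad <- colnames(dosages)[nas == nrow(dosages)]
    if (is.null(bad)) bad <- which(nas == nrow(dosages))
    abort(paste0("Fully missing variant(s): ", paste(bad, collapse = ", ")))
  }
  for (j in which(nas > 0)) {
    miss <- is.na(dosages[, j])
    dosages[miss, j] <- mean(dosages[!miss, j])
  }
  dosages
}

#' Intersect and order analysis samples
#'
#' The analysis sample is the intersection of genotype, methylation and
#' covariate sample ids, kept in genotype order.
#'
#' @param genotype_ids,methylation_ids,covariate_ids Character vectors of
#'   sample identifiers.
#' @return Character vector of retained ids, in genotype order.
#' @export
align_samples <- function(genotype_ids, methylation_ids, covariate_ids) {
  keep <- genotype_ids[genotype_ids %in% methylation_ids &
                         genotype_ids %in% covariate_ids]
  if (length(keep) == 0) abort("No samples shared across genotype, methylation and covariates.")
  keep
}

#' Normalize and residualize a methylation matrix
#'
#' Applies the rank-based inverse normal transform per probe (row), then
#' residualizes each probe on the covariates. This is the default
#' preprocessing path; passing covariates into the test's null model instead
#' gives identical p-values for the same covariate set.
#'
#' @param methylation Matrix, probes in rows, samples in columns.
#' @param covariates Data frame of numeric covariates (rows aligned with the
#'   methylation columns), or `NULL`.
#' @param rank_normal Apply the rank-inverse-normal transform first?
#' @return Matrix of the same shape on the analysis scale.
#' @export
preprocess_methylation <- function(methylation, covariates = NULL,
                                   rank_normal = TRUE) {
  m <- as.matrix(methylation)
  out <- t(apply(m, 1, function(y) {
    if (rank_normal) y <- rank_inverse_normal(y)
    if (!is.null(covariates)) y <- residualize(y, covariates)
    y
  }))
  dimnames(out) <- dimnames(m)
  out
}
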