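#' Two-locus linkage disequilibrium (D, D', r2)
#'
#' Estimates haplotype frequencies for a pair of variants and derives
#' \eqn{D = p_{AB} - p_A p_B}, the normalized \eqn{D' = |D| / D_{max}} and
#' \eqn{r^2}. For (near-)integer dosages the estimator is a two-locus EM on
#' unphased genotypes (the only ambiguous configuration is the double
#' heterozygote); fractional dosages fall back to a composite covariance
#' estimate \eqn{D = \mathrm{cov}(g_1, g_2) / 2}. D' is preferred over
#' \eqn{r^2} for rare-vs-common comparisons because the range of \eqn{r^2}
#' depends on the allele frequencies.
#'
#' @param g1,g2 Dosage vectors in \[0, 2\], both polymorphic.
#' @param max_iter,tol EM iteration cap and convergence tolerance.
#' @return Tibble with `D`, `D_prime`, `r2`, `method`
#'   (`"em_haplotype"` or `"composite"`).
#' @export
estimate_dprime <- function(g1, g2, max_iter = 50, tol = 1e-8) {
  g1 <- as.numeric(g1); g2 <- as.numeric(g2)
  if (length(g1) != length(g2)) abort("Dosage vectors must have equal length.")
  pA <- mean(g1) / 2; pB <- mean(g2) / 2
  if (var(g1) == 0 || var(g2) == 0 || pA %in% c(0, 1) || pB %in% c(0, 1)) {
    abort("Monomorphic variant: LD undefined.")
  }
  hard <- max(abs(g1 - round(g1))) < 1e-6 && max(abs(g2 - round(g2))) < 1e-6
  if (hard) {
    D <- em_haplotype_D(round(g1), round(g2), max_iter, tol)
    method <- "em_haplotype"
  } else {
    D <- cov(g1, g2) * (length(g1) - 1) / length(g1) / 2
    method <- "composite"
  }
  d_max <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  tibble(D = D,
         D_prime = if (d_max > 0) min(abs(D) / d_max, 1) else 0,
         r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)),
         method = method)
}

# EM over the AB haplotype frequency from unphased hard calls; returns D.
em_haplotype_D <- function(g1, g2, max_iter, tol) {
  n <- length(g1)
  counts <- table(factor(g1, levels = 0:2), factor(g2, levels = 0:2))
  pA <- mean(g1) / 2; pB <- mean(g2) / 2
  # haplotype frequencies: p11 = AB, p10 = Ab, p01 = aB, p00 = ab
  p11 <- pA * pB
  for (it in seq_len(max_iter)) {
    p10 <- pA - p11; p01 <- pB - p11; p00 <- 1 - pA - pB + p11
    # known haplotype counts from unambiguous genotypes
    nAB <- 2 * counts[3, 3] + counts[3, 2] + counts[2, 3]
    nAb <- 2 * counts[3, 1] + counts[3, 2] + counts[2, 1]
    naB <- 2 * counts[1, 3] + counts[1, 2] + counts[2, 3]
    nab <- 2 * counts[1, 1] + counts[1, 2] + counts[2, 1]
    dh <- counts[2, 2]  # double heterozygotes: AB/ab vs Ab/aB unresolved
    denom <- p11 * p00 + p10 * p01
    f <- if (denom > 0) p11 * p00 / denom else 0.5
    new_p11 <- (nAB + dh * f) / (2 * n)  # each AB/ab double het holds one AB haplotype
    if (abs(new_p11 - p11) < tol) {
      p11 <- new_p11
      break
    }
    p11 <- new_p11
  }
  p11 - pA * pB
}

#' Prune region variants in LD with an index SNP
#'
#' Removes every region variant whose D' with the index SNP meets the
#' threshold (default 0.8, inclusive) so that the remaining set cannot
#' merely tag the known single-variant mQTL. With several index SNPs the
#' maximum D' over indices is used. The region stays eligible for the
#' conditional test only if at least 2 variants remain.
#'
#' @param variants Tibble of region variants (`variant_id`, ...).
#' @param dosages Matrix, samples x variants (must cover `variants`).
#' @param index_dosages Vector, or samples x indices matrix, of index SNP
#'   dosages.
#' @param threshold D' removal threshold (inclusive).
#' @return The retained rows of `variants`, with a `d_prime` column (max
#'   over indices) and attribute `eligible`.
#' @export
prune_by_dprime <- function(variants, dosages, index_dosages,
                            threshold = 0.8) {
  variants <- as_tibble(variants)
  idx <- as.matrix(index_dosages)
  dp <- vapply(variants$variant_id, function(v) {
    max(vapply(seq_len(ncol(idx)), function(k) {
      estimate_dprime(dosages[, v], idx[, k])$D_prime
    }, numeric(1)))
  }, numeric(1))
  out <- mutate(variants, d_prime = unname(dp))
  out <- out[dp < threshold, , drop = FALSE]
  attr(out, "eligible") <- nrow(out) >= 2
  out
}

#' Kernel test conditioning on index SNP(s)
#'
#' Re-tests a (pruned) variant set with the known index SNP dosages appended
#' to the covariates, isolating rare-variant signal independent of the known
#' single-variant mQTL. A second pass for significant results can condition
#' on the full matrix of all index SNPs at the locus by passing them all.
#'
#' @inheritParams skat_test
#' @param index_dosages Vector or matrix of index SNP dosages (the
#'   conditioning covariates).
#' @param G_pruned Dosage matrix of the retained region variants.
#' @return An `rv_skat` object (see [skat_test()]).
#' @export
conditional_skat <- function(y, covariates = NULL, index_dosages, G_pruned,
                             a1 = 1, a2 = 25, ...) {
  idx <- as.matrix(index_dosages)
  colnames(idx) <- paste0("index_snp", seq_len(ncol(idx)))
  X <- if (is.null(covariates)) idx else
    cbind(as.matrix(as.data.frame(covariates)), idx)
  skat_test(y, X, G_pruned, a1 = a1, a2 = a2, ...)
}

#' Conditioning on a probe-overlapping variant
#'
#' Compares the region test with and without a probe-overlapping variant as
#' a covariate. A strong attenuation (conditional p much larger) indicates
#' the signal was an artifact of the overlapping variant rather than a
#' joint regional effect.
#'
#' @inheritParams conditional_skat
#' @param overlap_dosage Dosage vector of the variant overlapping the probe
#'   sequence (must be polymorphic in the analyzed subset).
#' @param G Dosage matrix of the region variants.
#' @return Tibble with `p_unconditional`, `p_conditional` and
#'   `log10_attenuation` (= log10 conditional p minus log10 unconditional
#'   p; positive means attenuation).
#' @export
probe_overlap_conditioning <- function(y, covariates = NULL, overlap_dosage,
                                       G, a1 = 1, a2 = 25) {
  if (var(as.numeric(overlap_dosage)) == 0) {
    abort("Overlapping variant is monomorphic in the analyzed subset.")
  }
  p0 <- skat_test(y, covariates, G, a1 = a1, a2 = a2)$p_value
  p1 <- conditional_skat(y, covariates, overlap_dosage, G,
                         a1 = a1, a2 = a2)$p_value
  tibble(p_unconditional = p0, p_conditional = p1,
         log10_attenuation = log10(p1) - log10(p0))
}
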