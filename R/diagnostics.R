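#' Greedy pairwise LD pruning
#'
#' Scans variants in column (position) order, keeping a variant only if its
#' squared correlation with every already-kept variant stays below the
#' threshold — i.e. the later member of any high-r2 pair is dropped.
#' Deterministic and idempotent.
#'
#' @param G Dosage matrix, samples x variants (columns in position order).
#' @param r2_threshold Removal threshold on r2 (inclusive).
#' @return Character vector of retained column names (or indices when
#'   unnamed).
#' @export
ld_prune <- function(G, r2_threshold = 0.8) {
  G <- as.matrix(G)
  if (ncol(G) == 0) abort("Need at least one variant.")
  ids <- colnames(G)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(G)))
  kept <- integer(0)
  for (j in seq_len(ncol(G))) {
    if (var(G[, j]) == 0) next
    high <- FALSE
    for (k in kept) {
      r2 <- suppressWarnings(cor(G[, j], G[, k])^2)
      if (is.finite(r2) && r2 >= r2_threshold) { high <- TRUE; break }
    }
    if (!high) kept <- c(kept, j)
  }
  ids[kept]
}

#' Leave-one-out stability analysis
#'
#' Re-runs the kernel test removing each (LD-pruned) variant in turn,
#' alongside the reference test on the full set. If the collapsed signal is
#' a genuinely joint effect, the \eqn{-\log_{10}} p-values stay strong for
#' every removal; a collapse upon removing one variant exposes a
#' single-variant driver (or an outlier carrier).
#'
#' @inheritParams skat_test
#' @param G Dosage matrix of the region's retained variants (at least 3, so
#'   each removal leaves a testable pair).
#' @return Tibble with one reference row (`removed = "none"`) plus one row
#'   per variant: `removed`, `n_variants_tested`, `p_value`,
#'   `neg_log10_p`, `reference_p`.
#' @export
leave_one_out <- function(y, covariates = NULL, G, a1 = 1, a2 = 25) {
  G <- as.matrix(G)
  if (ncol(G) < 3) {
    abort("Leave-one-out needs at least 3 variants so every removal leaves >= 2.")
  }
  ids <- colnames(G)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(G)))
  null <- fit_null(y, covariates)
  ref <- skat_test(y, covariates, G, a1 = a1, a2 = a2, null = null)
  rows <- lapply(seq_len(ncol(G)), function(j) {
    fit <- skat_test(y, covariates, G[, -j, drop = FALSE],
                     a1 = a1, a2 = a2, null = null)
    tibble(removed = ids[j], n_variants_tested = fit$n_variants,
           p_value = fit$p_value)
  })
  out <- bind_rows(
    tibble(removed = "none", n_variants_tested = ref$n_variants,
           p_value = ref$p_value),
    bind_rows(rows))
  mutate(out, neg_log10_p = -log10(.data$p_value),
         reference_p = ref$p_value)
}

#' Carrier / non-carrier methylation summaries
#'
#' For each variant, five-number summaries of the trait among carriers
#' (dosage at or above 0.5) and non-carriers, plus a count of carriers whose
#' trait value lies beyond 1.5 IQR of the full-sample quartiles — the data
#' behind carrier box-and-whisker outlier inspection.
#'
#' @param y Numeric trait vector.
#' @param G Dosage matrix, samples x variants.
#' @return Tibble with one row per variant: `variant_id`, `n_carriers`,
#'   carrier and non-carrier five-number summaries (`_min`, `_q1`, `_med`,
#'   `_q3`, `_max`), and `n_outlier_carriers`. Variants with zero carriers
#'   get `NA` carrier summaries.
#' @export
carrier_summary <- function(y, G) {
  G <- as.matrix(G)
  ids <- colnames(G)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(G)))
  qs <- quantile(y, c(0.25, 0.75))
  lo <- qs[1] - 1.5 * (qs[2] - qs[1])
  hi <- qs[2] + 1.5 * (qs[2] - qs[1])
  five <- function(v) {
    if (length(v) == 0) return(rep(NA_real_, 5))
    unname(quantile(v, c(0, 0.25, 0.5, 0.75, 1)))
  }
  bind_rows(lapply(seq_len(ncol(G)), function(j) {
    carrier <- G[, j] >= 0.5
    cf <- five(y[carrier]); nf <- five(y[!carrier])
    tibble(variant_id = ids[j], n_carriers = sum(carrier),
           carrier_min = cf[1], carrier_q1 = cf[2], carrier_med = cf[3],
           carrier_q3 = cf[4], carrier_max = cf[5],
           noncarrier_min = nf[1], noncarrier_q1 = nf[2],
           noncarrier_med = nf[3], noncarrier_q3 = nf[4],
           noncarrier_max = nf[5],
           n_outlier_carriers = sum(y[carrier] < lo | y[carrier] > hi))
  }))
}
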