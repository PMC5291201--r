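#' Run the collapsed-region mQTL scan
#'
#' Tests every region-probe pair with the weighted kernel association test.
#' The covariate-only null model is fitted once per probe and reused across
#' all regions paired with it (identical p-values to refitting, since the
#' null model does not depend on the region). Rows are emitted in
#' deterministic (region, probe) order regardless of input order; pairs whose
#' probe is missing from the methylation matrix are skipped with a warning.
#'
#' @param pairs Tibble from [enumerate_pairs()] (`region_id`, `probe_id`,
#'   `relation`).
#' @param regions Tibble from [region_variant_sets()]: must carry
#'   `region_id`, `variant_ids`, `eligible`.
#' @param methylation Matrix, probes x samples, on the analysis scale.
#' @param dosages Matrix, samples x variants.
#' @param covariates Data frame of numeric covariates aligned with the
#'   samples, or `NULL` (use when methylation is already residualized).
#' @param maf_cutoff Informational MAF tier recorded with the results.
#' @param p_threshold Significance threshold; a row passes iff
#'   `p_value < p_threshold` (strict).
#' @param a1,a2 Beta weight shape parameters.
#' @return Tibble with `region_id`, `tier`, `probe_id`, `relation`,
#'   `n_variants`, `p_value`, `p_method`, `passes_threshold`.
#' @export
run_scan <- function(pairs, regions, methylation, dosages, covariates = NULL,
                     maf_cutoff = 0.05, p_threshold = 1e-14,
                     a1 = 1, a2 = 25) {
  pairs <- arrange(as_tibble(pairs), .data$region_id, .data$probe_id)
  regions <- as_tibble(regions)
  empty <- tibble(region_id = character(), tier = character(),
                  probe_id = character(), relation = character(),
                  n_variants = integer(), p_value = numeric(),
                  p_method = character(), passes_threshold = logical())
  if (nrow(pairs) == 0) return(empty)
  tier <- if ("tier" %in% names(regions)) regions$tier[1] else NA_character_
  nulls <- new.env(parent = emptyenv())
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    pr <- pairs[i, ]
    reg <- regions[regions$region_id == pr$region_id, ]
    if (nrow(reg) != 1) abort(paste0("Unknown region: ", pr$region_id))
    if (!isTRUE(reg$eligible)) next
    if (!pr$probe_id %in% rownames(methylation)) {
      warn(paste0("Probe ", pr$probe_id, " missing from methylation matrix; pair skipped."))
      next
    }
    y <- methylation[pr$probe_id, ]
    if (is.null(nulls[[pr$probe_id]])) {
      nulls[[pr$probe_id]] <- fit_null(y, covariates)
    }
    G <- dosages[, reg$variant_ids[[1]], drop = FALSE]
    fit <- skat_test(y, covariates, G, a1 = a1, a2 = a2,
                     null = nulls[[pr$probe_id]])
    rows[[i]] <- tibble(
      region_id = pr$region_id, tier = tier, probe_id = pr$probe_id,
      relation = pr$relation, n_variants = fit$n_variants,
      p_value = fit$p_value, p_method = fit$p_method,
      passes_threshold = fit$p_value < p_threshold)
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) empty else out
}

#' Single-variant follow-up of a scan hit
#'
#' Regresses the probe's methylation on each of the region's variants in
#' turn, to check whether any single variant alone reaches the scan
#' threshold (in which case the collapsed signal is attributable to one
#' driver rather than a joint effect).
#'
#' @param hit One row of a [run_scan()] result (or anything with
#'   `region_id` and `probe_id`).
#' @inheritParams run_scan
#' @param p_threshold Threshold defining a single-variant driver.
#' @return Tibble with one row per variant (`variant_id`, `beta`, `se`,
#'   `p_value`) and attribute `drivers` (`TRUE` iff
#'   `min(p_value) < p_threshold`); see [drivers_flag()].
#' @export
followup_single_variants <- function(hit, regions, methylation, dosages,
                                     covariates = NULL, p_threshold = 1e-14) {
  regions <- as_tibble(regions)
  reg <- regions[regions$region_id == hit$region_id, ]
  if (nrow(reg) != 1) abort(paste0("Unknown region: ", hit$region_id))
  y <- methylation[hit$probe_id, ]
  ids <- reg$variant_ids[[1]]
  out <- bind_rows(lapply(ids, function(v) {
    res <- single_variant_regression(y, covariates, dosages[, v])
    mutate(res, variant_id = v, .before = 1)
  }))
  attr(out, "drivers") <- any(out$p_value < p_threshold)
  out
}

#' @rdname followup_single_variants
#' @param followup Result of [followup_single_variants()].
#' @export
drivers_flag <- function(followup) isTRUE(attr(followup, "drivers"))

#' Quantile-quantile points for a p-value set
#'
#' Pairs the sorted observed \eqn{-\log_{10} p} with the uniform-order
#' expectations \eqn{-\log_{10}(i / (m + 1))}. Zero p-values are floored at
#' `p_floor` and flagged.
#'
#' @param p_values Numeric vector of p-values in (0, 1\].
#' @param p_floor Floor applied to nonpositive p-values.
#' @return Tibble with `expected`, `observed` (both on the
#'   \eqn{-\log_{10}} scale) and `floored`.
#' @export
qq_points <- function(p_values, p_floor = 1e-300) {
  if (length(p_values) == 0) abort("No p-values supplied.")
  if (any(p_values > 1)) abort("p-values must lie in (0, 1].")
  floored <- p_values <= 0
  if (any(floored)) {
    warn(sprintf("%d p-value(s) at or below 0 floored at %g.",
                 sum(floored), p_floor))
    p_values[floored] <- p_floor
  }
  ord <- order(p_values)
  m <- length(p_values)
  tibble(expected = -log10(seq_len(m) / (m + 1)),
         observed = -log10(p_values[ord]),
         floored = floored[ord])
}

#' Re-evaluate hits in other datasets
#'
#' Re-tests each hit's region-probe pair in each further dataset (e.g. other
#' time points or replication cohorts) using only the variants available
#' there — unavailable variants are dropped, never replaced. Pairs with
#' fewer than 2 available variants are marked untestable.
#'
#' @param hits Tibble with `region_id` and `probe_id` (e.g. passing rows of
#'   [run_scan()]).
#' @param regions Region table with `region_id`, `variant_ids`.
#' @param datasets Named list; each element a list with `methylation`,
#'   `dosages`, and optionally `covariates`.
#' @param a1,a2 Beta weight shape parameters.
#' @return Tibble with one row per hit x dataset: `region_id`, `probe_id`,
#'   `dataset`, `n_variants`, `p_value`, `testable`.
#' @export
multi_timepoint_evaluation <- function(hits, regions, datasets,
                                       a1 = 1, a2 = 25) {
  regions <- as_tibble(regions)
  if (is.null(names(datasets)) || any(names(datasets) == "")) {
    abort("`datasets` must be a named list.")
  }
  rows <- list()
  for (ds_name in names(datasets)) {
    ds <- datasets[[ds_name]]
    for (i in seq_len(nrow(hits))) {
      h <- hits[i, ]
      reg <- regions[regions$region_id == h$region_id, ]
      avail <- intersect(reg$variant_ids[[1]], colnames(ds$dosages))
      testable <- length(avail) >= 2 && h$probe_id %in% rownames(ds$methylation)
      if (testable) {
        y <- ds$methylation[h$probe_id, ]
        fit <- skat_test(y, ds$covariates, ds$dosages[, avail, drop = FALSE],
                         a1 = a1, a2 = a2)
        p <- fit$p_value
        nv <- fit$n_variants
      } else {
        p <- NA_real_
        nv <- length(avail)
      }
      rows[[length(rows) + 1]] <- tibble(
        region_id = h$region_id, probe_id = h$probe_id, dataset = ds_name,
        n_variants = nv, p_value = p, testable = testable)
    }
  }
  bind_rows(rows)
}
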