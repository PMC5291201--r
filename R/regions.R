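#' Expand CpG islands to shore/shelf regions
#'
#' Pads island intervals symmetrically by tier: `island` adds nothing,
#' `island_shore` adds 2,000 bp (the shores) and `island_shore_shelf` adds
#' 4,000 bp (shores plus shelves) up- and downstream. Starts are clamped at
#' 0. Intervals are 0-based half-open throughout.
#'
#' @param islands Tibble with columns `chrom`, `start`, `end` (and typically
#'   `island_id`).
#' @param tier One of `"island"`, `"island_shore"`, `"island_shore_shelf"`.
#' @return `islands` with added columns `tier`, `region_start`, `region_end`.
#' @examples
#' expand_region(tibble::tibble(chrom = "chr1", start = 10000, end = 12000),
#'               "island_shore")
#' @export
expand_region <- function(islands, tier = c("island", "island_shore",
                                            "island_shore_shelf")) {
  tier <- match.arg(tier)
  islands <- as_tibble(islands)
  if (any(islands$start >= islands$end) || any(islands$start < 0)) {
    abort("Invalid island interval(s): need 0 <= start < end.")
  }
  pad <- region_pad(tier)
  islands %>%
    mutate(tier = tier,
           region_start = pmax(0, .data$start - pad),
           region_end = .data$end + pad)
}

region_pad <- function(tier) {
  switch(tier,
         island = 0,
         island_shore = 2000,
         island_shore_shelf = 4000,
         abort(paste0("Unknown tier: ", tier)))
}

#' Collapse variants into a region at a MAF cutoff
#'
#' Returns the variants whose position falls inside the expanded region
#' (half-open interval on the 0-based scale; a variant exactly at
#' `region_end` is excluded) with MAF at or below the cutoff. A region is
#' eligible for the collapsing test only when at least 2 variants qualify —
#' with a single variant the collapsing method has no benefit.
#'
#' @param variants Tibble with `variant_id`, `chrom`, `pos` (1-based), `maf`.
#' @param region One-row tibble/list with `chrom`, `region_start`,
#'   `region_end` (0-based half-open).
#' @param maf_cutoff MAF ceiling (inclusive), e.g. 0.05 or 0.01.
#' @return Tibble of qualifying variants with attribute `eligible`
#'   (`TRUE` iff at least 2 rows); see also [region_eligible()].
#' @export
collapse_variants <- function(variants, region, maf_cutoff = 0.05) {
  variants <- as_tibble(variants)
  pos0 <- variants$pos - 1  # 1-based position -> 0-based coordinate
  keep <- variants$chrom == region$chrom &
    pos0 >= region$region_start & pos0 < region$region_end &
    variants$maf <= maf_cutoff
  out <- variants[keep, , drop = FALSE]
  attr(out, "eligible") <- nrow(out) >= 2
  out
}

#' @rdname collapse_variants
#' @param collapsed Result of [collapse_variants()].
#' @export
region_eligible <- function(collapsed) {
  isTRUE(attr(collapsed, "eligible")) || nrow(collapsed) >= 2
}

#' Region-by-region collapsed variant sets
#'
#' Vectorized companion of [collapse_variants()]: one row per region with the
#' qualifying variant ids as a list-column, their count, and the eligibility
#' flag.
#'
#' @param regions Tibble from [expand_region()] with a `region_id` (or
#'   `island_id`) column.
#' @inheritParams collapse_variants
#' @return `regions` with added `variant_ids` (list), `n_variants`,
#'   `eligible`.
#' @export
region_variant_sets <- function(regions, variants, maf_cutoff = 0.05) {
  regions <- as_tibble(regions)
  sets <- purrr::map(seq_len(nrow(regions)), function(i) {
    collapse_variants(variants, regions[i, ], maf_cutoff)$variant_id
  })
  regions %>%
    mutate(variant_ids = sets,
           n_variants = lengths(sets),
           eligible = .data$n_variants >= 2)
}

#' Incremental eligibility counts per region tier
#'
#' Attributes each island to the narrowest tier at which its collapsed
#' variant set first reaches 2 qualifying variants, mirroring the
#' island / "+shore" / "+shelf" bookkeeping: an island eligible using the
#' island proper counts there only; one that needs the shores counts at the
#' shore tier; and so on. Islands never reaching 2 variants count nowhere.
#'
#' @param islands Tibble with `island_id`, `chrom`, `start`, `end`.
#' @inheritParams collapse_variants
#' @param detail If `TRUE`, return the per-island assignment instead of the
#'   per-tier summary.
#' @return Tibble with `tier` and `n_regions` (3 rows), or the per-island
#'   detail with columns `n_island`, `n_shore`, `n_shelf`,
#'   `first_eligible_tier`.
#' @export
tiered_eligibility <- function(islands, variants, maf_cutoff = 0.05,
                               detail = FALSE) {
  tiers <- c("island", "island_shore", "island_shore_shelf")
  counts <- lapply(tiers, function(tr) {
    region_variant_sets(expand_region(islands, tr), variants,
                        maf_cutoff)$n_variants
  })
  names(counts) <- tiers
  first_tier <- rep(NA_character_, nrow(as_tibble(islands)))
  for (tr in rev(tiers)) first_tier[counts[[tr]] >= 2] <- tr
  # rev() so narrower tiers overwrite wider ones
  det <- as_tibble(islands) %>%
    mutate(n_island = counts$island,
           n_shore = counts$island_shore,
           n_shelf = counts$island_shore_shelf,
           first_eligible_tier = first_tier)
  if (detail) return(det)
  tibble(tier = tiers,
         n_regions = unname(vapply(tiers, function(tr)
           sum(first_tier == tr, na.rm = TRUE), integer(1))))
}

#' Partition islands by proximity to known single-variant mQTLs
#'
#' Islands with a previously reported single-variant mQTL within
#' `exclusion_pad` of the island (inclusive distance) are routed to the
#' conditional analysis rather than the novel scan.
#'
#' @param islands Tibble with `chrom`, `start`, `end`.
#' @param known_mqtl Tibble with `snp_id`, `chrom`, `pos` (1-based), or
#'   `NULL`/empty for none.
#' @param exclusion_pad Distance in bp (default 5,000).
#' @return `islands` with a logical `conditional` column.
#' @export
exclude_prior_mqtl_regions <- function(islands, known_mqtl,
                                       exclusion_pad = 5000) {
  islands <- as_tibble(islands)
  if (is.null(known_mqtl) || nrow(as_tibble(known_mqtl)) == 0) {
    return(mutate(islands, conditional = FALSE))
  }
  known_mqtl <- as_tibble(known_mqtl)
  cond <- vapply(seq_len(nrow(islands)), function(i) {
    isl <- islands[i, ]
    same <- known_mqtl$chrom == isl$chrom
    if (!any(same)) return(FALSE)
    pos0 <- known_mqtl$pos[same] - 1
    d <- pmax(0, isl$start - pos0, pos0 - (isl$end - 1))
    any(d <= exclusion_pad)
  }, logical(1))
  mutate(islands, conditional = cond)
}

#' Enumerate cis/trans region-probe test pairs
#'
#' A pair is cis when the probe lies on the same chromosome within
#' `window_bp` of the expanded region's nearest edge (inclusive at exactly
#' the window); all other combinations — same-chromosome probes beyond the
#' window and every other-chromosome probe — are trans. The cis and trans
#' lists partition the full region x probe grid exactly.
#'
#' @param regions Tibble from [expand_region()] with `region_id`, `chrom`,
#'   `region_start`, `region_end`.
#' @param probes Tibble with `probe_id`, `chrom`, `pos` (1-based).
#' @param window_bp Cis window in bp (default 1e6).
#' @param relation Which pairs to return: `"cis"`, `"trans"` or `"both"`.
#' @return Tibble with `region_id`, `probe_id`, `relation`, `distance`
#'   (`NA` across chromosomes).
#' @export
enumerate_pairs <- function(regions, probes, window_bp = 1e6,
                            relation = c("cis", "trans", "both")) {
  relation <- match.arg(relation)
  regions <- as_tibble(regions)
  probes <- as_tibble(probes)
  if (anyNA(probes$pos)) {
    abort(paste0("Probe(s) without position: ",
                 paste(probes$probe_id[is.na(probes$pos)], collapse = ", ")))
  }
  grid <- tidyr::crossing(region_id = regions$region_id,
                          probe_id = probes$probe_id) %>%
    left_join(select(regions, "region_id", region_chrom = "chrom",
                     "region_start", "region_end"), by = "region_id") %>%
    left_join(select(probes, "probe_id", probe_chrom = "chrom", "pos"),
              by = "probe_id") %>%
    mutate(
      pos0 = .data$pos - 1,
      distance = ifelse(
        .data$region_chrom == .data$probe_chrom,
        pmax(0, .data$region_start - .data$pos0,
             .data$pos0 - (.data$region_end - 1)),
        NA_real_),
      relation = ifelse(!is.na(.data$distance) & .data$distance <= window_bp,
                        "cis", "trans")) %>%
    select("region_id", "probe_id", "relation", "distance") %>%
    arrange(.data$region_id, .data$probe_id)
  switch(relation,
         both = grid,
         cis = filter(grid, .data$relation == "cis"),
         trans = filter(grid, .data$relation == "trans"))
}

#' Trans-test bookkeeping
#'
#' Number of trans tests implied by a scan: all region x probe combinations
#' minus the cis pairs. Computed in double precision (exact for counts below
#' 2^53, far beyond genome scale).
#'
#' @param n_regions,n_probes,n_cis_pairs Counts.
#' @return The trans-pair count as a double.
#' @examples
#' trans_pair_count(8701, 294905, 12726079)
#' @export
trans_pair_count <- function(n_regions, n_probes, n_cis_pairs) {
  as.numeric(n_regions) * as.numeric(n_probes) - as.numeric(n_cis_pairs)
}
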