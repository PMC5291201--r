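#' Validate a coupled input bundle
#'
#' Consistency checks ahead of any computation: sample alignment across
#' genotypes / methylation / covariates, chromosome-name style consistency
#' across variants / islands / probes, and probe-manifest completeness.
#' Issues are reported, not thrown; `fatal` rows would abort a pipeline run.
#'
#' @param data List with `variants`, `dosages`, `islands`, `probes`,
#'   `methylation`, `covariates` (as produced by [read_fixture_set()] or
#'   [simulate_mqtl_data()]).
#' @return Tibble with `level` (`"fatal"`/`"warning"`), `check`, `message`;
#'   zero rows for a fully consistent bundle.
#' @export
validate_inputs <- function(data) {
  issues <- list()
  add <- function(level, check, message) {
    issues[[length(issues) + 1]] <<- tibble(level = level, check = check,
                                            message = message)
  }
  g_ids <- rownames(data$dosages)
  m_ids <- colnames(data$methylation)
  c_ids <- data$covariates$sample_id
  shared <- intersect(intersect(g_ids, m_ids), c_ids)
  if (length(shared) == 0) {
    add("fatal", "samples", "No samples shared across genotypes, methylation and covariates.")
  } else {
    dropped <- setdiff(union(union(g_ids, m_ids), c_ids), shared)
    if (length(dropped) > 0) {
      add("warning", "samples",
          paste0("Dropped by intersection: ", paste(dropped, collapse = ", ")))
    }
  }
  styles <- c(variants = chrom_style(data$variants$chrom),
              islands = chrom_style(data$islands$chrom),
              probes = chrom_style(data$probes$chrom))
  if (length(unique(styles)) > 1) {
    add("fatal", "chromosomes",
        paste0("Chromosome naming styles differ (",
               paste(names(styles), styles, sep = "=", collapse = ", "),
               "); normalize to one convention (e.g. strip or add 'chr')."))
  }
  if (anyNA(data$probes$pos)) {
    add("fatal", "probes",
        paste0("Probe(s) without position: ",
               paste(data$probes$probe_id[is.na(data$probes$pos)],
                     collapse = ", ")))
  }
  miss <- setdiff(rownames(data$methylation), data$probes$probe_id)
  if (length(miss) > 0) {
    add("warning", "probes",
        paste0("Methylation rows absent from the probe manifest: ",
               paste(miss, collapse = ", ")))
  }
  if (length(issues) == 0) {
    return(tibble(level = character(), check = character(),
                  message = character()))
  }
  bind_rows(issues)
}

chrom_style <- function(chrom) {
  if (all(grepl("^chr", chrom))) "chr-prefixed" else
    if (!any(grepl("^chr", chrom))) "bare" else "mixed"
}

#' Conditional analysis over known-mQTL regions
#'
#' For each island routed to the conditional set, collapses variants at the
#' MAF cutoff, removes those in high LD (D' at or above `dprime_threshold`)
#' with the locus's index SNP(s), and — when at least 2 variants remain —
#' runs the kernel test on the index-mQTL probe with the index dosages as
#' covariates.
#'
#' @param data Input bundle (see [validate_inputs()]).
#' @param known_mqtl Tibble with `snp_id`, `chrom`, `pos`, `probe_id`.
#' @param tier Region tier used for collapsing.
#' @param maf_cutoff MAF ceiling for the collapsed set.
#' @param dprime_threshold D' pruning threshold (inclusive removal).
#' @param covariates Covariate data frame (defaults to the bundle's,
#'   without `sample_id`).
#' @param exclusion_pad Distance defining "in close proximity".
#' @param a1,a2 Beta weight parameters.
#' @return Tibble: `island_id`, `probe_id`, `index_snps`, `n_before`,
#'   `n_after`, `eligible`, `p_conditional`.
#' @export
run_conditional_analysis <- function(data, known_mqtl,
                                     tier = "island_shore",
                                     maf_cutoff = 0.05,
                                     dprime_threshold = 0.8,
                                     covariates = NULL,
                                     exclusion_pad = 5000,
                                     a1 = 1, a2 = 25) {
  known_mqtl <- as_tibble(known_mqtl)
  if (nrow(known_mqtl) == 0) {
    return(tibble(island_id = character(), probe_id = character(),
                  index_snps = character(), n_before = integer(),
                  n_after = integer(), eligible = logical(),
                  p_conditional = numeric()))
  }
  islands <- exclude_prior_mqtl_regions(data$islands, known_mqtl,
                                        exclusion_pad)
  regions <- expand_region(islands[islands$conditional, ], tier)
  if (is.null(covariates)) covariates <- drop_sample_id(data$covariates)
  rows <- list()
  for (i in seq_len(nrow(regions))) {
    reg <- regions[i, ]
    pos0 <- known_mqtl$pos - 1
    near <- known_mqtl$chrom == reg$chrom &
      pmax(0, reg$start - pos0, pos0 - (reg$end - 1)) <= exclusion_pad
    idx <- known_mqtl[near, ]
    idx <- idx[idx$snp_id %in% colnames(data$dosages), ]
    if (nrow(idx) == 0) next
    collapsed <- collapse_variants(data$variants, reg, maf_cutoff)
    collapsed <- collapsed[!collapsed$variant_id %in% idx$snp_id, ]
    idx_dos <- data$dosages[, unique(idx$snp_id), drop = FALSE]
    pruned <- if (nrow(collapsed) > 0) {
      prune_by_dprime(collapsed, data$dosages, idx_dos, dprime_threshold)
    } else collapsed
    eligible <- nrow(pruned) >= 2
    for (pid in unique(idx$probe_id)) {
      p_cond <- NA_real_
      if (eligible && pid %in% rownames(data$methylation)) {
        fit <- conditional_skat(data$methylation[pid, ], covariates,
                                idx_dos,
                                data$dosages[, pruned$variant_id,
                                             drop = FALSE],
                                a1 = a1, a2 = a2)
        p_cond <- fit$p_value
      }
      rows[[length(rows) + 1]] <- tibble(
        island_id = reg$island_id, probe_id = pid,
        index_snps = paste(unique(idx$snp_id), collapse = ","),
        n_before = nrow(collapsed), n_after = nrow(pruned),
        eligible = eligible, p_conditional = p_cond)
    }
  }
  bind_rows(rows)
}

drop_sample_id <- function(covariates) {
  if (is.null(covariates)) return(NULL)
  cv <- as.data.frame(covariates)
  cv[, setdiff(names(cv), "sample_id"), drop = FALSE]
}

#' Run the full collapsed-mQTL pipeline
#'
#' Orchestrates the analysis end to end on an input bundle: input
#' validation, sample alignment, variant QC, per-probe rank-normalization,
#' region building with prior-mQTL exclusion, cis scan, single-variant
#' follow-up of hits, conditional analysis of the excluded regions, and Q-Q
#' data. Deterministic for a fixed bundle.
#'
#' @param data Input bundle: an `mqtl_sim` object, a [read_fixture_set()]
#'   list, or a fixture directory path.
#' @param tier Collapsing tier (default islands + shores, the tier that
#'   identifies most cis signals).
#' @param maf_cutoff MAF ceiling for collapsing (0.05 or 0.01).
#' @param p_threshold Scan significance threshold (strict `<`).
#' @param cis_window_bp Cis window (default 1 Mb, inclusive at the edge).
#' @param exclusion_pad Prior-mQTL exclusion distance (default 5 kb).
#' @param rank_normal Rank-inverse-normalize methylation per probe first?
#' @param hwe_min,maf_max,info_min Variant QC thresholds.
#' @param dprime_threshold D' pruning threshold for the conditional stage.
#' @param a1,a2 Beta weight shape parameters.
#' @param out_dir Optional directory: result tables are written as TSV plus
#'   a machine-readable `summary.json`.
#' @return Object of class `mqtl_run`: list with `regions`, `pairs`,
#'   `scan`, `followup`, `conditional`, `qq`, `tier_counts`, `summary`.
#' @export
run_end_to_end <- function(data, tier = "island_shore", maf_cutoff = 0.05,
                           p_threshold = 1e-14, cis_window_bp = 1e6,
                           exclusion_pad = 5000, rank_normal = TRUE,
                           hwe_min = 5e-7, maf_max = 0.05, info_min = 0.8,
                           dprime_threshold = 0.8, a1 = 1, a2 = 25,
                           out_dir = NULL) {
  if (is.character(data)) data <- read_fixture_set(data)
  if (inherits(data, "mqtl_sim")) {
    data <- list(variants = data$variants, dosages = data$dosages,
                 islands = data$islands, probes = data$probes,
                 methylation = data$methylation,
                 covariates = data$covariates,
                 known_mqtl = sim_known_mqtl(data))
  }
  report <- validate_inputs(data)
  if (any(report$level == "fatal")) {
    abort(paste0("Input validation failed: ",
                 paste(report$message[report$level == "fatal"],
                       collapse = " | ")))
  }
  samples <- align_samples(rownames(data$dosages),
                           colnames(data$methylation),
                           data$covariates$sample_id)
  dosages <- impute_missing_dosages(data$dosages[samples, , drop = FALSE])
  meth <- data$methylation[, samples, drop = FALSE]
  covariates <- drop_sample_id(
    data$covariates[match(samples, data$covariates$sample_id), ])
  variants <- data$variants
  variants$maf <- unname(dosage_maf(dosages)[variants$variant_id])
  variants <- filter_variants(variants, hwe_min, maf_max, info_min)
  meth <- preprocess_methylation(meth, covariates = NULL,
                                 rank_normal = rank_normal)
  known <- data$known_mqtl
  islands <- exclude_prior_mqtl_regions(data$islands, known, exclusion_pad)
  novel <- expand_region(islands[!islands$conditional, ], tier)
  novel$region_id <- novel$island_id
  regions <- region_variant_sets(novel, variants, maf_cutoff)
  pairs <- enumerate_pairs(regions, data$probes, window_bp = cis_window_bp,
                           relation = "both")
  cis_pairs <- filter(pairs, .data$relation == "cis")
  scan <- run_scan(cis_pairs, regions, meth, dosages, covariates,
                   maf_cutoff = maf_cutoff, p_threshold = p_threshold,
                   a1 = a1, a2 = a2)
  hits <- filter(scan, .data$passes_threshold)
  followup <- purrr::map(seq_len(nrow(hits)), function(i) {
    fu <- followup_single_variants(hits[i, ], regions, meth, dosages,
                                   covariates, p_threshold)
    mutate(fu, region_id = hits$region_id[i], probe_id = hits$probe_id[i],
           drivers = drivers_flag(fu))
  }) %>% bind_rows()
  conditional <- run_conditional_analysis(
    list(variants = variants, dosages = dosages, islands = data$islands,
         probes = data$probes, methylation = meth, covariates = data$covariates),
    known, tier = tier, maf_cutoff = maf_cutoff,
    dprime_threshold = dprime_threshold, covariates = covariates,
    exclusion_pad = exclusion_pad, a1 = a1, a2 = a2)
  qq <- if (nrow(scan) > 0) qq_points(scan$p_value) else
    tibble(expected = numeric(), observed = numeric(), floored = logical())
  tier_counts <- tiered_eligibility(islands[!islands$conditional, ],
                                    variants, maf_cutoff)
  summary <- list(
    n_samples = length(samples),
    n_variants_post_qc = nrow(variants),
    n_islands = nrow(data$islands),
    n_conditional_islands = sum(islands$conditional),
    n_eligible_regions = sum(regions$eligible),
    tier_counts = setNames(as.list(tier_counts$n_regions),
                           tier_counts$tier),
    n_cis_pairs = nrow(cis_pairs),
    n_trans_pairs = sum(pairs$relation == "trans"),
    n_tested = nrow(scan),
    n_hits = nrow(hits))
  out <- structure(
    list(regions = regions, pairs = pairs, scan = scan,
         followup = followup, conditional = conditional, qq = qq,
         tier_counts = tier_counts, summary = summary,
         validation = report),
    class = "mqtl_run")
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

write_run <- function(run, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  readr::write_tsv(select(run$regions, -"variant_ids"), p("regions.tsv"),
                   progress = FALSE)
  readr::write_tsv(run$scan, p("scan_cis.tsv"), progress = FALSE)
  readr::write_tsv(run$followup, p("followup.tsv"), progress = FALSE)
  readr::write_tsv(run$conditional, p("conditional.tsv"), progress = FALSE)
  readr::write_tsv(run$qq, p("qq_points.tsv"), progress = FALSE)
  jsonlite::write_json(run$summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(out_dir)
}

#' @export
print.mqtl_run <- function(x, ...) {
  s <- x$summary
  cat("Collapsed rare-variant mQTL run\n")
  cat(sprintf("  samples: %d   variants post-QC: %d\n",
              s$n_samples, s$n_variants_post_qc))
  cat(sprintf("  eligible regions: %d   cis pairs tested: %d   hits: %d\n",
              s$n_eligible_regions, s$n_tested, s$n_hits))
  invisible(x)
}
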