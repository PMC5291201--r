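#' Simulation configuration
#'
#' Bundles the generative parameters for a coupled genotype / annotation /
#' methylation fixture with the statistical structure the mQTL analysis
#' assumes: rare variants in LD blocks around CpG islands, probes nearby
#' (plus distant probes to exercise trans logic), covariates, and planted
#' region effects with known truth.
#'
#' Defaults emulate the study conditions at desk scale: 800 samples,
#' variants at MAF 1-5 percent, normalized methylation with unit noise.
#'
#' @param n_samples Number of samples (>= 2).
#' @param n_islands Number of CpG islands.
#' @param island_length_range Island length range in bp.
#' @param inter_island_gap_range Gap range between consecutive islands in bp;
#'   the minimum must exceed 8,000 so shelf-expanded regions stay disjoint.
#' @param variants_per_region_range Range of rare-variant counts per island
#'   neighbourhood.
#' @param maf_range Target minor allele frequency range, within (0, 0.5).
#' @param ld_block_size Variants per correlated block (1 = independent).
#' @param probe_offset_range Probe position offset relative to the island
#'   midpoint, in bp.
#' @param effect_scenarios List of [effect_spec()] objects.
#' @param noise_sd Standard deviation of the Gaussian noise term.
#' @param covariate_count Number of covariates (first is a binary batch
#'   indicator, the rest standard normal).
#' @param n_trans_probes Number of probes placed more than 1 Mb from every
#'   island.
#' @param seed Integer seed; identical configs give byte-identical fixtures.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 800, n_islands = 12,
                       island_length_range = c(500, 3000),
                       inter_island_gap_range = c(60000, 120000),
                       variants_per_region_range = c(4, 8),
                       maf_range = c(0.01, 0.05),
                       ld_block_size = 2,
                       probe_offset_range = c(-100000, 100000),
                       effect_scenarios = list(),
                       noise_sd = 1, covariate_count = 2,
                       n_trans_probes = 2, seed = 1) {
  if (n_samples < 2) abort("Need at least 2 samples.")
  if (maf_range[1] <= 0 || maf_range[2] >= 0.5 || maf_range[1] > maf_range[2]) {
    abort("`maf_range` must lie within (0, 0.5).")
  }
  if (any(island_length_range <= 0)) abort("Island lengths must be positive.")
  if (inter_island_gap_range[1] <= 8000) {
    abort("Minimum inter-island gap must exceed 8,000 bp so shelf-expanded regions stay disjoint.")
  }
  for (sc in effect_scenarios) {
    if (!inherits(sc, "effect_spec")) abort("`effect_scenarios` must be effect_spec objects.")
    if (sc$region_index < 1 || sc$region_index > n_islands) {
      abort(sprintf("Effect scenario references region %d but only %d islands exist.",
                    sc$region_index, n_islands))
    }
  }
  structure(
    list(n_samples = n_samples, n_islands = n_islands,
         island_length_range = island_length_range,
         inter_island_gap_range = inter_island_gap_range,
         variants_per_region_range = variants_per_region_range,
         maf_range = maf_range, ld_block_size = ld_block_size,
         probe_offset_range = probe_offset_range,
         effect_scenarios = effect_scenarios,
         noise_sd = noise_sd, covariate_count = covariate_count,
         n_trans_probes = n_trans_probes, seed = seed),
    class = "sim_config")
}

#' Planted effect scenario
#'
#' Describes the generative effect at one island's probe. Modes:
#' * `null` — no genetic effect.
#' * `collapsed` — several rare variants with (possibly mixed-sign) effects.
#' * `single_variant` — one rare variant carries the whole effect.
#' * `single_plus_collapsed` — a common index SNP effect plus an independent
#'   collapsed rare-variant effect.
#' * `tagged_only` — only the common index SNP has an effect; the region's
#'   rare variants sit on the index haplotype (high D-prime) and merely tag it.
#' * `probe_overlap` — one rare variant drives the probe signal, emulating a
#'   variant overlapping the probe sequence.
#'
#' @param region_index Which island (1-based) carries the effect.
#' @param mode One of the modes above.
#' @param effect_sizes Optional per-variant effect vector for the region's
#'   rare variants (recycled/truncated to the realized variant count). `NULL`
#'   uses mode-specific defaults.
#' @param index_snp_maf Allele frequency of the common index SNP, for modes
#'   that involve one.
#' @param index_beta Effect size of the index SNP.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(region_index,
                        mode = c("null", "collapsed", "single_variant",
                                 "single_plus_collapsed", "tagged_only",
                                 "probe_overlap"),
                        effect_sizes = NULL, index_snp_maf = 0.2,
                        index_beta = 1.2) {
  mode <- match.arg(mode)
  if (!is.null(effect_sizes)) {
    if (mode == "null" && any(effect_sizes != 0)) {
      abort("null mode requires all effect sizes to be zero.")
    }
    if (mode %in% c("collapsed", "single_plus_collapsed") &&
        sum(effect_sizes != 0) < 2) {
      abort("collapsed modes require at least 2 nonzero effect sizes.")
    }
  }
  structure(list(region_index = region_index, mode = mode,
                 effect_sizes = effect_sizes, index_snp_maf = index_snp_maf,
                 index_beta = index_beta),
            class = "effect_spec")
}

needs_index <- function(mode) mode %in% c("single_plus_collapsed", "tagged_only")

# Mixed signs alternate across (not within) LD blocks of the default block
# size 2, so planted effects do not cancel along shared haplotypes.
default_betas <- function(mode, nv, index_beta) {
  pad <- function(b) c(b, rep(0, nv - length(b)))
  switch(mode,
         null = rep(0, nv),
         collapsed = pad(rep_len(c(0.7, 0.7, -0.7, -0.7), min(nv, 4))),
         single_variant = c(2.5, rep(0, nv - 1)),
         single_plus_collapsed = pad(rep_len(c(0.7, 0.7, -0.7, -0.7),
                                             min(nv, 4))),
         tagged_only = rep(0, nv),
         probe_overlap = c(2.5, rep(0, nv - 1)))
}

#' Simulate island and probe annotations
#'
#' Places non-overlapping islands along one chromosome separated by gaps
#' large enough to keep shelf-expanded regions disjoint, puts one probe near
#' each island midpoint (within the configured offset), and adds probes more
#' than 1 Mb beyond the last island to exercise trans classification.
#'
#' @param config A [sim_config()].
#' @return List with `islands` (tibble: `island_id`, `chrom`, `start`,
#'   `end`; 0-based half-open, sorted) and `probes` (tibble: `probe_id`,
#'   `chrom`, `pos` (1-based), `island_id` — `NA` for trans probes).
#' @export
simulate_annotations <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  k <- config$n_islands
  lens <- round(runif(k, config$island_length_range[1],
                      config$island_length_range[2]))
  gaps <- round(runif(k, config$inter_island_gap_range[1],
                      config$inter_island_gap_range[2]))
  starts <- numeric(k)
  ends <- numeric(k)
  cursor <- 10000
  for (i in seq_len(k)) {
    starts[i] <- cursor + gaps[i]
    ends[i] <- starts[i] + lens[i]
    cursor <- ends[i]
  }
  islands <- tibble(island_id = sprintf("isl_%03d", seq_len(k)),
                    chrom = "chr1", start = starts, end = ends)
  mids <- round((starts + ends) / 2)
  offs <- round(runif(k, config$probe_offset_range[1],
                      config$probe_offset_range[2]))
  probes <- tibble(probe_id = sprintf("cg%08d", seq_len(k)),
                   chrom = "chr1",
                   pos = pmax(1, mids + offs),
                   island_id = islands$island_id)
  if (config$n_trans_probes > 0) {
    tp <- tibble(
      probe_id = sprintf("cg%08d", 90000000 + seq_len(config$n_trans_probes)),
      chrom = "chr1",
      pos = ends[k] + 4000 + 1.2e6 + (seq_len(config$n_trans_probes) - 1) * 5e4,
      island_id = NA_character_)
    probes <- bind_rows(probes, tp)
  }
  list(islands = islands, probes = probes)
}

#' Simulate genotypes around islands
#'
#' Generates phased haplotypes from a latent-haplotype block model: variants
#' within a block share a latent ancestral haplotype and carry their minor
#' allele only on copies of it (thinned to hit each variant's target MAF),
#' giving positive within-block LD; blocks are mutually independent. Modes
#' that involve a common index SNP add one per scenario region; in
#' `tagged_only` scenarios the region's rare alleles are placed on the index
#' haplotype itself, so their D-prime with the index SNP is 1 by
#' construction. Variants realizing a minor-allele count of 0 are resampled;
#' a variant whose expected minor-allele count is below 1 is an error.
#'
#' @param config A [sim_config()].
#' @param annotations Result of [simulate_annotations()]; generated
#'   internally when `NULL`.
#' @return List with `variants` (tibble: `variant_id`, `chrom`, `pos`,
#'   `maf` (realized, folded), `target_maf`, `info_score`, `hwe_p`,
#'   `island_id`, `is_index`), `dosages` (samples x variants),
#'   `haplotypes` (2n x variants phased truth), and `annotations`.
#' @export
simulate_genotypes <- function(config, annotations = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(annotations)) annotations <- simulate_annotations(config)
  islands <- annotations$islands
  n <- config$n_samples
  min_maf <- config$maf_range[1]
  if (2 * n * min_maf < 1) {
    abort(sprintf(
      "n_samples = %d too small: expected minor-allele count %.2f < 1 at MAF %.4g.",
      n, 2 * n * min_maf, min_maf))
  }
  scen_by_region <- scenario_map(config)
  hap_cols <- list(); meta <- list()
  for (i in seq_len(nrow(islands))) {
    isl <- islands[i, ]
    nv <- sample(seq(config$variants_per_region_range[1],
                     config$variants_per_region_range[2]), 1)
    sc <- scen_by_region[[isl$island_id]]
    # scenario regions keep their variants within island + shores so planted
    # effects are collapsible at the island_shore tier; null regions scatter
    # variants out into (and beyond) the shelves to exercise the tier logic
    spread <- if (is.null(sc) || sc$mode == "null") 4500 else 2000
    lo <- max(1, isl$start - spread)
    hi <- isl$end + spread
    pos <- sort(sample(seq(lo + 1, hi), nv))  # 1-based positions
    mafs <- runif(nv, config$maf_range[1], config$maf_range[2])
    idx_hap <- NULL
    if (!is.null(sc) && needs_index(sc$mode)) {
      idx_hap <- draw_polymorphic(function() rbinom(2 * n, 1, sc$index_snp_maf),
                                  paste0("idx_", isl$island_id))
    }
    tagged <- !is.null(sc) && sc$mode == "tagged_only"
    blocks <- split(seq_len(nv), ceiling(seq_len(nv) / config$ld_block_size))
    haps <- matrix(0L, 2 * n, nv)
    for (b in blocks) {
      q <- min(0.5, 1.5 * max(mafs[b]))
      latent <- if (tagged) idx_hap else rbinom(2 * n, 1, q)
      q_eff <- if (tagged) sc$index_snp_maf else q
      for (j in b) {
        if (2 * n * mafs[j] < 1) {
          abort(sprintf("Variant %s_%02d: expected minor-allele count < 1.",
                        isl$island_id, j))
        }
        haps[, j] <- draw_polymorphic(
          function() latent * rbinom(2 * n, 1, min(1, mafs[j] / q_eff)),
          sprintf("%s_v%02d", isl$island_id, j))
      }
    }
    ids <- sprintf("%s_v%02d", isl$island_id, seq_len(nv))
    v_meta <- tibble(variant_id = ids, chrom = isl$chrom, pos = pos,
                     target_maf = mafs, island_id = isl$island_id,
                     is_index = FALSE)
    if (!is.null(idx_hap)) {
      haps <- cbind(haps, idx_hap)
      v_meta <- bind_rows(v_meta, tibble(
        variant_id = paste0("idx_", isl$island_id), chrom = isl$chrom,
        pos = round((isl$start + isl$end) / 2) + 1,
        target_maf = sc$index_snp_maf, island_id = isl$island_id,
        is_index = TRUE))
    }
    hap_cols[[i]] <- haps
    meta[[i]] <- v_meta
  }
  haplotypes <- do.call(cbind, hap_cols)
  variants <- bind_rows(meta)
  colnames(haplotypes) <- variants$variant_id
  odd <- seq(1, 2 * n, by = 2)
  dosages <- haplotypes[odd, , drop = FALSE] + haplotypes[odd + 1, , drop = FALSE]
  dosages <- matrix(as.numeric(dosages), nrow = n,
                    dimnames = list(sprintf("S%04d", seq_len(n)),
                                    variants$variant_id))
  variants$maf <- unname(dosage_maf(dosages))
  variants$info_score <- runif(nrow(variants), 0.81, 1)
  variants$hwe_p <- unname(apply(dosages, 2, hwe_chisq_p))
  variants <- select(variants, "variant_id", "chrom", "pos", "maf",
                     "target_maf", "info_score", "hwe_p", "island_id",
                     "is_index")
  list(variants = variants, dosages = dosages, haplotypes = haplotypes,
       annotations = annotations)
}

draw_polymorphic <- function(draw, name, tries = 200) {
  for (t in seq_len(tries)) {
    h <- draw()
    if (sum(h) > 0 && sum(h) < length(h)) return(h)
  }
  abort(paste0("Variant ", name, " could not realize a polymorphic draw."))
}

scenario_map <- function(config) {
  out <- setNames(vector("list", config$n_islands),
                  sprintf("isl_%03d", seq_len(config$n_islands)))
  for (sc in config$effect_scenarios) {
    out[[sc$region_index]] <- sc
  }
  out
}

# Chi-square goodness-of-fit test of Hardy-Weinberg proportions on hard calls.
hwe_chisq_p <- function(dos) {
  g <- round(dos)
  n <- length(g)
  p <- mean(g) / 2
  obs <- c(sum(g == 0), sum(g == 1), sum(g == 2))
  exp <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  keep <- exp > 0
  stat <- sum((obs[keep] - exp[keep])^2 / exp[keep])
  pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Simulate methylation from the planted linear model
#'
#' For each probe, generates
#' \eqn{y = \alpha_0 + X\alpha + G\beta + \epsilon}, with Gaussian noise of
#' standard deviation `noise_sd`, the covariate effects \eqn{\alpha} fixed,
#' and \eqn{G\beta} determined by the probe's island scenario (zero for null
#' and trans probes). Records the complete generative truth per probe.
#'
#' @param genotypes Result of [simulate_genotypes()].
#' @param annotations Result of [simulate_annotations()] (defaults to the
#'   one embedded in `genotypes`).
#' @param config The [sim_config()].
#' @return List with `methylation` (probes x samples matrix), `covariates`
#'   (tibble with `sample_id` first), and `truth` (tibble, one row per
#'   probe: mode, contributing variant ids, beta vector, covariate
#'   coefficients, noise sd).
#' @export
simulate_methylation <- function(genotypes, annotations = NULL, config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(annotations)) annotations <- genotypes$annotations
  n <- config$n_samples
  m <- config$covariate_count
  X <- NULL; alpha <- numeric(0)
  if (m > 0) {
    X <- cbind(batch = rbinom(n, 1, 0.5))
    if (m > 1) {
      X <- cbind(X, matrix(rnorm(n * (m - 1)), n,
                           dimnames = list(NULL, paste0("cov", seq_len(m - 1)))))
    }
    alpha <- rep(0.25, m)
  }
  scen_by_region <- scenario_map(config)
  probes <- annotations$probes
  dos <- genotypes$dosages
  vars <- genotypes$variants
  meth <- matrix(NA_real_, nrow(probes), n,
                 dimnames = list(probes$probe_id, rownames(dos)))
  truth_rows <- vector("list", nrow(probes))
  for (i in seq_len(nrow(probes))) {
    pid <- probes$probe_id[i]
    iid <- probes$island_id[i]
    sc <- if (!is.na(iid)) scen_by_region[[iid]] else NULL
    mode <- if (is.null(sc)) "null" else sc$mode
    rare_ids <- vars$variant_id[!is.na(vars$island_id) &
                                  vars$island_id %in% iid & !vars$is_index]
    nv <- length(rare_ids)
    beta <- rep(0, nv)
    idx_id <- NA_character_; idx_beta <- 0
    if (!is.null(sc)) {
      beta <- if (is.null(sc$effect_sizes)) {
        default_betas(mode, nv, sc$index_beta)
      } else {
        missing_ref <- length(sc$effect_sizes) > nv
        if (missing_ref) {
          abort(sprintf(
            "Scenario for %s references %d variants but only %d exist after generation.",
            iid, length(sc$effect_sizes), nv))
        }
        c(sc$effect_sizes, rep(0, nv - length(sc$effect_sizes)))
      }
      if (needs_index(mode)) {
        idx_id <- paste0("idx_", iid)
        idx_beta <- sc$index_beta
      }
    }
    g_part <- 0
    if (nv > 0 && any(beta != 0)) {
      g_part <- as.vector(dos[, rare_ids, drop = FALSE] %*% beta)
    }
    if (!is.na(idx_id)) g_part <- g_part + idx_beta * dos[, idx_id]
    xb <- if (is.null(X)) 0 else as.vector(X %*% alpha)
    meth[i, ] <- xb + g_part + rnorm(n, 0, config$noise_sd)
    truth_rows[[i]] <- tibble(
      probe_id = pid, island_id = iid, mode = mode,
      variant_ids = list(rare_ids), beta = list(beta),
      index_variant = idx_id, index_beta = idx_beta,
      alpha0 = 0, alpha = list(alpha), noise_sd = config$noise_sd)
  }
  covariates <- tibble(sample_id = rownames(dos))
  if (!is.null(X)) covariates <- bind_cols(covariates, as_tibble(X))
  list(methylation = meth, covariates = covariates,
       truth = bind_rows(truth_rows))
}

#' Simulate a complete coupled fixture
#'
#' Runs annotation, genotype and methylation generation under the config's
#' seed. Identical configs (including the seed) yield identical objects and,
#' through [write_fixture_set()], byte-identical files.
#'
#' @param config A [sim_config()].
#' @return An object of class `mqtl_sim`: list with `config`, `islands`,
#'   `probes`, `variants`, `dosages`, `haplotypes`, `methylation`,
#'   `covariates`, `truth`.
#' @examples
#' sim <- simulate_mqtl_data(sim_config(n_samples = 60, n_islands = 3,
#'                                      maf_range = c(0.02, 0.05)))
#' dim(sim$dosages)
#' @export
simulate_mqtl_data <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    ann <- simulate_annotations(config)
    gen <- simulate_genotypes(config, ann)
    met <- simulate_methylation(gen, ann, config)
    structure(
      list(config = config, islands = ann$islands, probes = ann$probes,
           variants = gen$variants, dosages = gen$dosages,
           haplotypes = gen$haplotypes, methylation = met$methylation,
           covariates = met$covariates, truth = met$truth),
      class = "mqtl_sim")
  })
}

#' Known single-variant mQTL list implied by a fixture
#'
#' For scenarios that involve a common index SNP, returns the index-SNP /
#' probe records in the format the conditional analysis consumes.
#'
#' @param sim An `mqtl_sim` object.
#' @return Tibble with `snp_id`, `chrom`, `pos`, `probe_id`.
#' @export
sim_known_mqtl <- function(sim) {
  tr <- sim$truth[!is.na(sim$truth$index_variant), ]
  if (nrow(tr) == 0) {
    return(tibble(snp_id = character(), chrom = character(),
                  pos = numeric(), probe_id = character()))
  }
  v <- sim$variants
  tibble(snp_id = tr$index_variant,
         chrom = v$chrom[match(tr$index_variant, v$variant_id)],
         pos = v$pos[match(tr$index_variant, v$variant_id)],
         probe_id = tr$probe_id)
}
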