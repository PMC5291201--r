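test_that("perfect allelic coupling yields D-prime of 1", {
  # minor alleles of both variants always co-occur on the same haplotypes
  g <- c(rep(2, 3), rep(1, 6), rep(0, 91))
  ld <- estimate_dprime(g, g)
  expect_equal(ld$D_prime, 1, tolerance = 1e-6)
  expect_equal(ld$method, "em_haplotype")
  # coupling with different frequencies: rare variant rides a common one
  g_common <- c(rep(1, 30), rep(0, 70))
  g_rare <- c(rep(1, 5), rep(0, 95))
  expect_equal(estimate_dprime(g_common, g_rare)$D_prime, 1,
               tolerance = 1e-6)
})

test_that("independent variants show small average D-prime", {
  set.seed(91)
  dps <- replicate(30, {
    g1 <- rbinom(4000, 2, 0.1)
    g2 <- rbinom(4000, 2, 0.1)
    estimate_dprime(g1, g2)$D_prime
  })
  expect_lt(mean(dps), 0.12)
})

test_that("EM D-prime recovers the phased-haplotype truth", {
  cfg <- sim_config(n_samples = 1000, n_islands = 4, ld_block_size = 3,
                    variants_per_region_range = c(6, 6), seed = 92)
  sim <- simulate_mqtl_data(cfg)
  hap_dprime <- function(h1, h2) {
    pA <- mean(h1); pB <- mean(h2)
    D <- mean(h1 * h2) - pA * pB
    dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
      min(pA * pB, (1 - pA) * (1 - pB))
    abs(D) / dmax
  }
  v <- sim$variants[sim$variants$island_id == "isl_001", ]
  checked <- 0
  for (i in 1:2) for (j in (i + 1):3) {
    a <- v$variant_id[i]; b <- v$variant_id[j]
    truth <- hap_dprime(sim$haplotypes[, a], sim$haplotypes[, b])
    em <- estimate_dprime(sim$dosages[, a], sim$dosages[, b])$D_prime
    expect_lt(abs(em - truth), 0.02)
    checked <- checked + 1
  }
  expect_equal(checked, 3)
})

test_that("D-prime is symmetric and invariant to allele recoding", {
  set.seed(93)
  h <- rbinom(2000, 1, 0.3)
  g1 <- (h * rbinom(2000, 1, 0.5))[1:1000] + (h * rbinom(2000, 1, 0.5))[1001:2000]
  set.seed(94)
  g2 <- rbinom(1000, 2, 0.2)
  a <- estimate_dprime(g1, g2)
  b <- estimate_dprime(g2, g1)
  expect_equal(a$D_prime, b$D_prime, tolerance = 1e-9)
  flip <- estimate_dprime(2 - g1, g2)
  expect_equal(flip$D_prime, a$D_prime, tolerance = 1e-9)
  expect_equal(estimate_dprime(g1, 2 - g2)$D_prime, a$D_prime,
               tolerance = 1e-9)
  expect_error(estimate_dprime(rep(0, 100), rbinom(100, 2, 0.2)),
               "Monomorphic")
})

test_that("fractional dosages use the composite estimator", {
  set.seed(95)
  g1 <- pmin(pmax(rbinom(500, 2, 0.2) + rnorm(500, 0, 0.05), 0), 2)
  g2 <- rbinom(500, 2, 0.2)
  expect_equal(estimate_dprime(g1, g2)$method, "composite")
})

test_that("pruning removes variants at or above the D-prime threshold", {
  set.seed(96)
  idx <- rbinom(800, 2, 0.25)
  # tagging variant: minor allele only among index carriers
  tag <- as.integer(idx >= 1 & rbinom(800, 1, 0.15) == 1)
  indep <- rbinom(800, 2, 0.05)
  dos <- cbind(tag = tag, indep = indep, idx = idx)
  v <- tibble::tibble(variant_id = c("tag", "indep"))
  pruned <- prune_by_dprime(v, dos, idx)
  expect_equal(pruned$variant_id, "indep")
  expect_false(region_eligible(pruned))
  # removal is inclusive at the threshold itself
  dp_indep <- estimate_dprime(indep, idx)$D_prime
  at <- prune_by_dprime(v, dos, idx, threshold = dp_indep)
  expect_false("indep" %in% at$variant_id)
  # everything retained when independent of the index
  all_indep <- cbind(a = rbinom(800, 2, 0.05), b = rbinom(800, 2, 0.05))
  keep <- prune_by_dprime(tibble::tibble(variant_id = c("a", "b")),
                          all_indep, idx)
  expect_equal(keep$variant_id, c("a", "b"))
  expect_true(region_eligible(keep))
})

test_that("conditional testing separates independent from tagged signal", {
  scen <- list(effect_spec(1, "single_plus_collapsed"),
               effect_spec(2, "tagged_only"))
  sim <- simulate_mqtl_data(sim_config(n_samples = 600, n_islands = 4,
                                       effect_scenarios = scen, seed = 97))
  covs <- sim$covariates[, -1, drop = FALSE]
  meth <- preprocess_methylation(sim$methylation)
  get_region <- function(iid) {
    v <- filter_variants(sim$variants)
    reg <- expand_region(sim$islands[sim$islands$island_id == iid, ],
                         "island_shore")
    collapse_variants(v, reg)
  }
  # independent rare-variant effect survives conditioning on the index SNP
  r1 <- get_region("isl_001")
  pr1 <- prune_by_dprime(r1, sim$dosages, sim$dosages[, "idx_isl_001"])
  expect_true(region_eligible(pr1))
  fit1 <- conditional_skat(meth["cg00000001", ], covs,
                           sim$dosages[, "idx_isl_001"],
                           sim$dosages[, pr1$variant_id])
  expect_lt(fit1$p_value, 1e-6)
  # tagged-only region loses everything to pruning...
  r2 <- get_region("isl_002")
  pr2 <- prune_by_dprime(r2, sim$dosages, sim$dosages[, "idx_isl_002"])
  expect_false(region_eligible(pr2))
  # ...and even unpruned, conditioning on the index removes the signal
  fit2 <- conditional_skat(meth["cg00000002", ], covs,
                           sim$dosages[, "idx_isl_002"],
                           sim$dosages[, r2$variant_id])
  expect_gt(fit2$p_value, 1e-3)
  # collinear index is rejected
  expect_error(
    conditional_skat(meth["cg00000001", ],
                     cbind(covs, dup = sim$dosages[, "idx_isl_001"]),
                     sim$dosages[, "idx_isl_001"],
                     sim$dosages[, pr1$variant_id]),
    "rank deficient")
})

test_that("conditioning on an irrelevant covariate barely moves the p-value", {
  set.seed(98)
  n <- 500
  G <- make_G(n, rep(0.04, 4))
  y <- rnorm(n) + as.vector(G %*% c(0.5, 0.5, -0.5, -0.5))
  p0 <- skat_test(y, G = G)$p_value
  z <- rnorm(n)  # orthogonal to y and G by construction
  p1 <- conditional_skat(y, NULL, z, G)$p_value
  expect_lt(abs(log10(p1) - log10(p0)), 0.1 * abs(log10(p0)))
})

test_that("probe-overlap conditioning flags artifact-driven signal", {
  scen <- list(effect_spec(3, "probe_overlap"))
  sim <- simulate_mqtl_data(sim_config(n_samples = 500, n_islands = 4,
                                       effect_scenarios = scen, seed = 99))
  covs <- sim$covariates[, -1, drop = FALSE]
  meth <- preprocess_methylation(sim$methylation)
  truth <- sim$truth[sim$truth$mode == "probe_overlap", ]
  overlap_id <- truth$variant_ids[[1]][which(truth$beta[[1]] != 0)]
  region_ids <- truth$variant_ids[[1]]
  y <- meth[truth$probe_id, ]
  res <- probe_overlap_conditioning(y, covs, sim$dosages[, overlap_id],
                                    sim$dosages[, region_ids])
  expect_lt(res$p_unconditional, 1e-8)
  expect_gt(res$log10_attenuation, 2)
  # a variant unrelated to the probe does not attenuate the signal
  unrelated <- sim$variants$variant_id[sim$variants$island_id == "isl_001"][1]
  res2 <- probe_overlap_conditioning(y, covs, sim$dosages[, unrelated],
                                     sim$dosages[, region_ids])
  expect_lt(abs(res2$log10_attenuation), 1)
  expect_error(
    probe_overlap_conditioning(y, covs, rep(0, 500),
                               sim$dosages[, region_ids]),
    "monomorphic")
})
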