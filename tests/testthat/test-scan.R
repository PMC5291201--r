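make_scan_world <- function(seed = 81, n_samples = 400, scenarios = list()) {
  sim <- simulate_mqtl_data(sim_config(n_samples = n_samples, n_islands = 8,
                                       effect_scenarios = scenarios,
                                       seed = seed))
  variants <- filter_variants(sim$variants)
  regions <- expand_region(sim$islands, "island_shore")
  regions$region_id <- regions$island_id
  regions <- region_variant_sets(regions, variants)
  pairs <- enumerate_pairs(regions[regions$eligible, ], sim$probes,
                           relation = "cis")
  meth <- preprocess_methylation(sim$methylation)
  covs <- sim$covariates[, -1, drop = FALSE]
  list(sim = sim, regions = regions, pairs = pairs, meth = meth, covs = covs)
}

test_that("a planted collapsed effect is the only pair passing Bonferroni", {
  w <- make_scan_world(scenarios = list(effect_spec(3, "collapsed")))
  alpha <- 0.05 / nrow(w$pairs)
  scan <- run_scan(w$pairs, w$regions, w$meth, w$sim$dosages, w$covs,
                   p_threshold = alpha)
  hits <- scan[scan$passes_threshold, ]
  expect_equal(nrow(hits), 1)
  expect_equal(hits$region_id, "isl_003")
  expect_equal(hits$probe_id, w$sim$truth$probe_id[w$sim$truth$mode == "collapsed"])
})

test_that("a rare-tier cutoff below the planted MAFs removes the signal", {
  # effects planted at MAF 2-5 percent are invisible to a 1 percent scan
  sim <- simulate_mqtl_data(sim_config(
    n_samples = 400, n_islands = 8, maf_range = c(0.02, 0.05),
    effect_scenarios = list(effect_spec(3, "collapsed")), seed = 82))
  variants <- filter_variants(sim$variants)
  regions <- expand_region(sim$islands, "island_shore")
  regions$region_id <- regions$island_id
  regions1 <- region_variant_sets(regions, variants, maf_cutoff = 0.01)
  pairs <- enumerate_pairs(regions1[regions1$eligible, ], sim$probes,
                           relation = "cis")
  scan <- run_scan(pairs, regions1, preprocess_methylation(sim$methylation),
                   sim$dosages, sim$covariates[, -1, drop = FALSE],
                   maf_cutoff = 0.01, p_threshold = 1e-10)
  expect_false(any(scan$passes_threshold))
})

test_that("scan output is deterministic, cached, and order-invariant", {
  w <- make_scan_world(seed = 83)
  scan1 <- run_scan(w$pairs, w$regions, w$meth, w$sim$dosages, w$covs)
  # shuffled pair order gives the identical table
  set.seed(1)
  scan2 <- run_scan(w$pairs[sample(nrow(w$pairs)), ], w$regions, w$meth,
                    w$sim$dosages, w$covs)
  expect_equal(scan1, scan2)
  # per-probe null caching matches independent refits pair by pair
  for (i in sample(nrow(scan1), 5)) {
    row <- scan1[i, ]
    reg <- w$regions[w$regions$region_id == row$region_id, ]
    fit <- skat_test(w$meth[row$probe_id, ], w$covs,
                     w$sim$dosages[, reg$variant_ids[[1]], drop = FALSE])
    expect_equal(row$p_value, fit$p_value, tolerance = 1e-12)
  }
  expect_equal(nrow(run_scan(w$pairs[0, ], w$regions, w$meth,
                             w$sim$dosages, w$covs)), 0)
})

test_that("pairs with probes missing from the matrix are skipped with a warning", {
  w <- make_scan_world(seed = 84)
  meth_missing <- w$meth[-1, , drop = FALSE]
  dropped <- rownames(w$meth)[1]
  expect_warning(
    scan <- run_scan(w$pairs, w$regions, meth_missing, w$sim$dosages, w$covs),
    dropped)
  expect_false(dropped %in% scan$probe_id)
})

test_that("single-variant follow-up distinguishes joint from driver signals", {
  w <- make_scan_world(seed = 85, scenarios = list(
    effect_spec(2, "collapsed"), effect_spec(5, "single_variant")))
  scan <- run_scan(w$pairs, w$regions, w$meth, w$sim$dosages, w$covs,
                   p_threshold = 1e-6)
  hit_c <- scan[scan$region_id == "isl_002" & scan$passes_threshold, ][1, ]
  hit_s <- scan[scan$region_id == "isl_005" & scan$passes_threshold, ][1, ]
  fu_c <- followup_single_variants(hit_c, w$regions, w$meth, w$sim$dosages,
                                   w$covs, p_threshold = 1e-14)
  fu_s <- followup_single_variants(hit_s, w$regions, w$meth, w$sim$dosages,
                                   w$covs, p_threshold = 1e-14)
  expect_false(drivers_flag(fu_c))
  expect_true(drivers_flag(fu_s))
  reg <- w$regions[w$regions$region_id == "isl_002", ]
  expect_equal(nrow(fu_c), length(reg$variant_ids[[1]]))
})

test_that("qq points pair sorted observations with uniform expectations", {
  qq <- qq_points(c(0.5, 0.1, 0.9))
  expect_equal(qq$expected, -log10(c(1, 2, 3) / 4))
  expect_equal(qq$observed, -log10(c(0.1, 0.5, 0.9)))
  one <- qq_points(0.2)
  expect_equal(one$expected, -log10(1 / 2))
  expect_warning(fl <- qq_points(c(0.5, 0)), "floored")
  expect_true(any(fl$floored))
  expect_error(qq_points(c(0.5, 1.2)), "0, 1")
  set.seed(86)
  u <- qq_points(runif(5000))
  # uniform sample hugs the identity line within a KS-style band
  expect_lt(max(abs(10^(-u$observed) - 10^(-u$expected))), 1.63 / sqrt(5000))
})

test_that("multi-dataset evaluation uses only the variants each dataset has", {
  scenarios <- list(effect_spec(3, "collapsed"))
  w <- make_scan_world(seed = 87, scenarios = scenarios)
  scan <- run_scan(w$pairs, w$regions, w$meth, w$sim$dosages, w$covs,
                   p_threshold = 1e-6)
  hits <- scan[scan$passes_threshold, ]
  expect_gte(nrow(hits), 1)
  # second time point: same genotypes and truth, fresh noise
  truth <- w$sim$truth[w$sim$truth$mode == "collapsed", ]
  y_new <- as.vector(w$sim$dosages[, truth$variant_ids[[1]]] %*%
                       truth$beta[[1]]) + rnorm(400)
  meth_b <- w$meth
  meth_b[truth$probe_id, ] <- rank_inverse_normal(y_new)
  full <- list(methylation = meth_b, dosages = w$sim$dosages,
               covariates = w$covs)
  region_ids <- w$regions$variant_ids[[match("isl_003", w$regions$region_id)]]
  missing_one <- list(methylation = meth_b,
                      dosages = w$sim$dosages[, -match(region_ids[1],
                                                       colnames(w$sim$dosages))],
                      covariates = w$covs)
  none <- list(methylation = meth_b,
               dosages = w$sim$dosages[, 0, drop = FALSE],
               covariates = w$covs)
  res <- multi_timepoint_evaluation(
    hits, w$regions,
    list(refresh = full, missing_one = missing_one, none = none))
  r_full <- res[res$dataset == "refresh", ]
  expect_true(all(r_full$testable))
  expect_true(all(r_full$p_value < 1e-4))  # planted hits replicate
  r_miss <- res[res$dataset == "missing_one", ]
  expect_equal(r_miss$n_variants, r_full$n_variants - 1L)
  expect_true(all(r_miss$testable))
  r_none <- res[res$dataset == "none", ]
  expect_false(any(r_none$testable))
  expect_true(all(is.na(r_none$p_value)))
})
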