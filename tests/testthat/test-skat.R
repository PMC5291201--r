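test_that("Beta-density weights match the closed form and its shape", {
  # density of Beta(1, 25) at x is 25 (1 - x)^24
  expect_equal(beta_weights(0.01), 25 * 0.99^24, tolerance = 1e-12)
  expect_equal(beta_weights(c(0.1, 0.3), a1 = 1, a2 = 1), c(1, 1))
  w <- beta_weights(c(0.01, 0.05))
  expect_gt(w[1], w[2])
  expect_equal(beta_weights(c(0.01, 0.05), custom_weights = c(2, 3)), c(2, 3))
  expect_error(beta_weights(0), "0, 0.5")
  expect_error(beta_weights(0.6), "0, 0.5")
  expect_error(beta_weights(0.1, a1 = -1), "positive")
})

test_that("null model stores OLS residuals orthogonal to the design", {
  set.seed(21)
  X <- data.frame(a = rnorm(100), b = rnorm(100), c = rnorm(100))
  y <- rnorm(100)
  null <- fit_null(y, X)
  for (j in seq_len(3)) {
    expect_lt(abs(sum(null$residuals * X[[j]])), 1e-8 * 100)
  }
  expect_equal(sum(null$residuals^2) / (100 - 4), null$sigma2)
  # intercept-only: residuals are centered y
  n0 <- fit_null(y)
  expect_equal(n0$residuals, y - mean(y))
})

test_that("null model rejects degenerate designs", {
  set.seed(22)
  x <- rnorm(50)
  expect_error(fit_null(2 * x + 1, data.frame(x = x)), "degenerate residual variance")
  expect_error(fit_null(rnorm(50), data.frame(a = x, b = 2 * x)),
               "rank deficient")
})

test_that("kernel statistic handles degenerate genotype columns", {
  set.seed(23)
  y <- rnorm(80)
  null <- fit_null(y)
  expect_error(kernel_statistic(null, matrix(0, 80, 3), rep(1, 3)),
               "No testable variants")
  G <- cbind(rbinom(80, 2, 0.2), 0)
  expect_warning(ks <- kernel_statistic(null, G, c(1, 1)), "zero-variance")
  expect_equal(ks$n_variants, 1L)
  # duplicated column (perfect LD) stays computable
  g <- rbinom(80, 2, 0.2)
  ks2 <- kernel_statistic(null, cbind(g, g), c(1, 1))
  expect_true(is.finite(quadform_pvalue(ks2$Q, ks2$lambda)$p_value))
})

test_that("quadratic-form tail reproduces chi-square quantiles and scaling", {
  # 1-df and 2-df closed forms at the 0.05 quantile, exact to 4 decimals
  expect_equal(quadform_pvalue(3.841459, 1)$p_value, 0.05, tolerance = 1e-4)
  expect_equal(quadform_pvalue(7.682918, 2)$p_value, 0.05, tolerance = 1e-4)
  expect_equal(quadform_pvalue(5.991465, c(1, 1))$p_value, 0.05,
               tolerance = 1e-4)
  expect_error(quadform_pvalue(3, numeric(0)), "Empty")
})

test_that("quadratic-form tail agrees with a Monte-Carlo oracle", {
  lambda <- c(3, 1, 0.5)
  set.seed(31)
  draws <- as.vector(cbind(rchisq(1e6, 1), rchisq(1e6, 1),
                           rchisq(1e6, 1)) %*% lambda)
  p_mc <- mean(draws >= 10)
  se <- sqrt(p_mc * (1 - p_mc) / 1e6)
  res <- quadform_pvalue(10, lambda)
  expect_equal(res$method, "exact_quadform")
  expect_lt(abs(res$p_value - p_mc), 3 * se)
})

test_that("moment-matched fallback is monotone and log-scale stable", {
  lambda <- c(2, 1, 0.3, 0.1)
  qs <- c(5, 20, 80, 200, 400)
  ps <- vapply(qs, function(q)
    quadform_pvalue(q, lambda, method = "moment")$p_value, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_true(all(ps > 0))
  expect_lt(ps[length(ps)], 1e-30)
  # floor applies
  expect_equal(quadform_pvalue(1e6, lambda, method = "moment",
                               p_floor = 1e-300)$p_value, 1e-300)
})

test_that("single-variant unit-weight kernel test equals the score test", {
  set.seed(33)
  for (rep in 1:5) {
    g <- rbinom(250, 2, runif(1, 0.05, 0.3))
    y <- rnorm(250) + runif(1, 0, 0.4) * g
    fit <- skat_test(y, G = matrix(g), weights = 1)
    null <- fit_null(y)
    gp <- g - mean(g)
    p_score <- pchisq(sum(gp * y)^2 / (null$sigma2 * sum(gp^2)), df = 1,
                      lower.tail = FALSE)
    expect_equal(fit$p_value, p_score, tolerance = 1e-6)
  }
})

test_that("kernel test is invariant to sample order and allele coding", {
  set.seed(34)
  n <- 200
  X <- data.frame(a = rnorm(n))
  G <- make_G(n, c(0.03, 0.05, 0.1))
  y <- rnorm(n) + 0.4 * G[, 1]
  p0 <- skat_test(y, X, G)$p_value
  ord <- sample(n)
  expect_equal(skat_test(y[ord], X[ord, , drop = FALSE], G[ord, ])$p_value,
               p0, tolerance = 1e-10)
  G_flip <- G
  G_flip[, 2] <- 2 - G_flip[, 2]  # swap minor/major coding of one variant
  expect_equal(skat_test(y, X, G_flip)$p_value, p0, tolerance = 1e-10)
})

test_that("pre-residualizing the trait leaves the test unchanged", {
  set.seed(35)
  n <- 150
  X <- data.frame(batch = rbinom(n, 1, 0.5), pc = rnorm(n))
  G <- make_G(n, c(0.04, 0.04, 0.08))
  y <- rnorm(n) + 0.3 * X$pc + 0.5 * G[, 1]
  p_direct <- skat_test(y, X, G)$p_value
  p_resid <- skat_test(residualize(y, X), X, G)$p_value
  expect_equal(p_resid, p_direct, tolerance = 1e-12)
})

test_that("mixed-sign region effects favor the kernel test over a burden sum", {
  # with conflicting effect directions a signed burden score cancels
  set.seed(36)
  n <- 500
  G <- make_G(n, rep(0.04, 4))
  y <- rnorm(n) + as.vector(G %*% c(0.8, -0.8, 0.8, -0.8))
  p_kernel <- skat_test(y, G = G)$p_value
  w <- beta_weights(dosage_maf(G))
  burden <- as.vector(G %*% w)
  p_burden <- single_variant_regression(y, g = burden)$p_value
  expect_lt(p_kernel, p_burden)
})

test_that("permutation oracle is reproducible and bounded below", {
  set.seed(37)
  G <- make_G(150, c(0.1, 0.2))
  y <- rnorm(150) + 1.5 * G[, 1]  # overwhelming signal
  pp <- permutation_pvalue(y, G = G, n_perm = 500, seed = 9)
  expect_equal(pp$p_value, 1 / 501)
  pp2 <- permutation_pvalue(y, G = G, n_perm = 500, seed = 9)
  expect_identical(pp$p_value, pp2$p_value)
  expect_error(permutation_pvalue(y, G = G, n_perm = 50), "at least 100")
})

test_that("analytic and permutation p-values agree on moderate instances", {
  set.seed(38)
  for (i in 1:4) {
    G <- make_G(200, runif(4, 0.1, 0.4))
    y <- rnorm(200) + as.vector(G %*% rnorm(4, 0, 0.1))
    a <- skat_test(y, G = G)$p_value
    pp <- permutation_pvalue(y, G = G, n_perm = 20000, seed = i)$p_value
    if (a >= 0.001 && a <= 0.5) {
      se3 <- 3 * sqrt((1 - pp) / (20000 * pp)) / log(10)
      expect_lt(abs(log10(a) - log10(pp)), max(se3, 0.02))
    }
  }
})

test_that("single-variant regression recovers exact and degenerate cases", {
  g <- rep(c(0, 1, 2), length.out = 20)
  fit <- suppressWarnings(single_variant_regression(2 * g, g = g))
  expect_equal(fit$beta, 2, tolerance = 1e-10)
  expect_lt(fit$p_value, 1e-200)
  expect_error(single_variant_regression(rnorm(20), g = rep(1, 20)),
               "zero variance")
  set.seed(39)
  g2 <- rbinom(50, 2, 0.3)
  expect_error(
    single_variant_regression(rnorm(50), data.frame(x = g2), g2),
    "rank deficient")
})

test_that("null p-values are uniform and power is monotone in effect size", {
  set.seed(40)
  ps <- replicate(400, {
    G <- make_G(150, runif(3, 0.05, 0.2))
    skat_test(rnorm(150), G = G)$p_value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 1e-3)
  # scaling every |beta| up (same noise seeds) should not raise the median p
  med_p <- vapply(c(0, 0.4, 0.8), function(b) {
    ps <- vapply(1:40, function(i) {
      set.seed(1000 + i)
      G <- make_G(200, rep(0.05, 4))
      eps <- rnorm(200)
      y <- eps + as.vector(G %*% (b * c(1, -1, 1, -1)))
      skat_test(y, G = G)$p_value
    }, numeric(1))
    median(ps)
  }, numeric(1))
  expect_true(all(diff(med_p) <= 0))
})

test_that("tidy and glance summarize fitted test objects", {
  set.seed(41)
  G <- make_G(120, c(0.1, 0.2))
  fit <- skat_test(rnorm(120), G = G)
  td <- tidy(fit)
  expect_named(td, c("statistic", "p_value", "p_method", "n_variants"))
  expect_equal(td$n_variants, 2L)
  gl <- glance(fit)
  expect_equal(gl$n_samples, 120L)
})
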