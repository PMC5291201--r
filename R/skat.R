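#' Beta-density variant weights
#'
#' Computes the per-variant weight \eqn{w_j = f(\mathrm{MAF}_j; a_1, a_2)}
#' where \eqn{f} is the Beta density. With the default shape parameters
#' (`a1 = 1`, `a2 = 25`) the weight decreases strictly in minor allele
#' frequency, so rarer variants contribute more to the kernel.
#'
#' @param maf Numeric vector of minor allele frequencies, each in (0, 0.5].
#' @param a1,a2 Positive Beta shape parameters.
#' @param custom_weights Optional numeric vector overriding the Beta weights
#'   (recycled checks apply: must match `length(maf)`).
#' @return Numeric vector of weights, one per variant.
#' @examples
#' beta_weights(c(0.01, 0.05))
#' @export
beta_weights <- function(maf, a1 = 1, a2 = 25, custom_weights = NULL) {
  if (!is.null(custom_weights)) {
    if (length(custom_weights) != length(maf)) {
      abort("`custom_weights` must have one entry per variant.")
    }
    if (any(custom_weights < 0)) abort("`custom_weights` must be non-negative.")
    return(as.numeric(custom_weights))
  }
  if (a1 <= 0 || a2 <= 0) abort("Beta shape parameters must be positive.")
  if (any(!is.finite(maf)) || any(maf <= 0) || any(maf > 0.5)) {
    abort("Minor allele frequencies must lie in (0, 0.5].")
  }
  dbeta(maf, a1, a2)
}

#' Fit the covariate-only null model
#'
#' Ordinary least squares of the trait on an intercept plus covariates. The
#' fitted object stores the residual vector, the residual variance
#' \eqn{\hat\sigma^2 = \mathrm{RSS}/(n - \mathrm{rank})} and the QR
#' decomposition of the design, which is reused to project genotype matrices
#' onto the covariate-orthogonal space. One null model per probe serves every
#' region tested against that probe.
#'
#' @param y Numeric trait vector (for mQTL scans: normalized methylation).
#' @param covariates Optional data frame or matrix of numeric covariates
#'   (no intercept column; one is added). `NULL` fits intercept only.
#' @return An object of class `rv_null`.
#' @export
fit_null <- function(y, covariates = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  X <- null_design(covariates, n)
  if (n <= ncol(X) + 1) abort("Need more samples than covariates + 1.")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    abort(paste0("Covariate design is rank deficient; collinear columns: ",
                 paste(bad, collapse = ", ")))
  }
  res <- qr.resid(qrX, y)
  sigma2 <- sum(res^2) / (n - qrX$rank)
  if (!is.finite(sigma2) || sigma2 <= 1e-12 * max(mean(y^2), 1e-12)) {
    abort("degenerate residual variance: trait is (numerically) fully explained by covariates")
  }
  structure(
    list(qr = qrX, residuals = res, sigma2 = sigma2, n = n, rank = qrX$rank,
         coefficients = qr.coef(qrX, y)),
    class = "rv_null"
  )
}

null_design <- function(covariates, n) {
  if (is.null(covariates)) {
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  }
  X <- as.matrix(as.data.frame(covariates))
  if (!is.numeric(X)) abort("Covariates must be numeric.")
  if (nrow(X) != n) abort("Covariate rows must match the trait length.")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  cbind(`(Intercept)` = 1, X)
}

#' Kernel statistic and null spectrum
#'
#' Forms the weighted linear kernel \eqn{K = G W^2 G'} from mean-centered
#' dosage columns and returns the score-type quadratic form
#' \eqn{Q = r' K r / (2\hat\sigma^2)} together with the eigenvalues
#' \eqn{\lambda} of the covariate-projected, identically scaled kernel, so
#' that under the null \eqn{Q \sim \sum_i \lambda_i \chi^2_1}.
#'
#' Zero-variance genotype columns are dropped with a warning; if none remain
#' the call fails. Perfectly collinear columns (e.g. duplicated variants) are
#' tolerated — the spectrum simply contains (near-)duplicate mass.
#'
#' @param null An `rv_null` object from [fit_null()].
#' @param G Dosage matrix, samples in rows, variants in columns, values in
#'   \[0, 2\].
#' @param weights Per-variant weights (see [beta_weights()]).
#' @return List with `Q`, `lambda`, `n_variants` (columns actually used),
#'   `kept` (logical per input column).
#' @export
kernel_statistic <- function(null, G, weights) {
  stopifnot(inherits(null, "rv_null"))
  G <- as.matrix(G)
  if (nrow(G) != null$n) abort("Genotype rows must match the null-model samples.")
  if (ncol(G) != length(weights)) abort("Need one weight per genotype column.")
  keep <- apply(G, 2, function(g) var(g) > 0)
  if (!any(keep)) abort("No testable variants: all genotype columns have zero variance.")
  if (!all(keep)) {
    warn(sprintf("Dropping %d zero-variance genotype column(s).", sum(!keep)))
  }
  B <- weighted_centered(G[, keep, drop = FALSE], weights[keep])
  r <- null$residuals
  Q <- sum(as.vector(crossprod(B, r))^2) / (2 * null$sigma2)
  Bp <- qr.resid(null$qr, B)
  # Under the null, r'Kr ~ sigma^2 * sum(eig(B'P0B) chi2_1); dividing Q by
  # sigma2-hat means the matching spectrum is eig(B'P0B)/2 — the estimate
  # normalizes the statistic, not the eigenvalues.
  A <- crossprod(Bp) / 2
  lambda <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  lambda <- pmax(lambda, 0)
  lambda <- lambda[lambda > 1e-10 * max(lambda)]
  list(Q = Q, lambda = lambda, n_variants = ncol(B), kept = keep)
}

weighted_centered <- function(G, w) {
  Gc <- sweep(G, 2, colMeans(G), `-`)
  sweep(Gc, 2, w, `*`)
}

#' Tail probability of a positive mixture of chi-squares
#'
#' Computes \eqn{P(\sum_i \lambda_i \chi^2_{1,i} \ge Q)}. The primary
#' algorithm inverts the characteristic function numerically (Imhof-type
#' integration); when the inversion fails, disagrees with its own error
#' estimate, or the tail falls below the reliable range of double-precision
#' inversion (about 1e-10), a moment-matched noncentral chi-square
#' approximation takes over. The fallback is monotone in `Q` and evaluated on
#' the log scale, so extremely small tails (the mQTL scan reports p-values
#' down to 1e-24 and beyond) remain ordered and finite. The returned p-value
#' is floored at `p_floor`.
#'
#' @param Q Observed quadratic-form statistic (non-negative scalar).
#' @param lambda Non-negative eigenvalue vector, at least one positive.
#' @param method `"auto"` (default), `"imhof"` to force the numeric
#'   inversion, or `"moment"` to force the moment-matched approximation.
#' @param p_floor Minimum reportable p-value.
#' @return List with `p_value` and `method` (one of `"exact_quadform"`,
#'   `"moment_matched"`).
#' @export
quadform_pvalue <- function(Q, lambda, method = c("auto", "imhof", "moment"),
                            p_floor = 1e-300) {
  method <- match.arg(method)
  lambda <- as.numeric(lambda)
  lambda <- lambda[lambda > 0]
  if (length(lambda) == 0) abort("Empty eigenvalue spectrum.")
  if (!is.finite(Q) || Q < 0) abort("Q must be a non-negative number.")
  if (method != "moment") {
    if (diff(range(lambda)) <= 1e-12 * max(lambda)) {
      # equal eigenvalues: Q / lambda is exactly chi-square
      p <- pchisq(Q / lambda[1], df = length(lambda), lower.tail = FALSE)
      return(list(p_value = max(min(p, 1), p_floor), method = "exact_quadform"))
    }
    p <- imhof_tail(Q, lambda)
    ok <- !is.null(p) && is.finite(p) && p > 1e-10 && p <= 1
    if (ok) {
      return(list(p_value = max(min(p, 1), p_floor), method = "exact_quadform"))
    }
    if (method == "imhof") {
      abort("Numeric inversion failed or underflowed; use method = 'auto' or 'moment'.")
    }
  }
  p <- liu_tail(Q, lambda)
  list(p_value = max(min(p, 1), p_floor), method = "moment_matched")
}

# Characteristic-function inversion for P(sum lambda_i chi2_1 >= Q).
imhof_tail <- function(Q, lambda) {
  theta <- function(u) {
    0.5 * colSums(atan(outer(lambda, u))) - 0.5 * Q * u
  }
  rho <- function(u) {
    exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
  }
  integrand <- function(u) {
    out <- sin(theta(u)) / (u * rho(u))
    # limit as u -> 0 is (sum(lambda) - Q) / 2
    out[u == 0] <- (sum(lambda) - Q) / 2
    out
  }
  val <- tryCatch(
    integrate(integrand, lower = 0, upper = Inf, subdivisions = 5000L,
              rel.tol = 1e-6, abs.tol = 1e-9, stop.on.error = FALSE),
    error = function(e) NULL
  )
  if (is.null(val) || val$message != "OK") return(NULL)
  p <- 0.5 + val$value / pi
  if (val$abs.error > max(1e-6, abs(p) * 1e-3)) return(NULL)
  p
}

# Moment-matched (mean/variance/skewness/kurtosis) noncentral chi-square tail,
# evaluated with log.p for stability far in the tail.
liu_tail <- function(Q, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2); c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    d <- s1 * a^3 - a^2
    l <- a^2 - 2 * d
  } else {
    l <- 1 / s2
    a <- sqrt(l)
    d <- 0
  }
  mu_q <- c1
  sigma_q <- sqrt(2 * c2)
  mu_x <- l + d
  sigma_x <- sqrt(2) * a
  x <- (Q - mu_q) / sigma_q * sigma_x + mu_x
  log_p <- pchisq(x, df = l, ncp = d, lower.tail = FALSE, log.p = TRUE)
  exp(log_p)
}

#' Weighted kernel association test for a variant set
#'
#' End-to-end variance-component score test of a quantitative trait against a
#' set of (rare) variants: fits (or reuses) the covariate-only null model,
#' weights variants by the Beta density of their sample minor allele
#' frequency, forms the weighted linear kernel and evaluates the
#' mixture-of-chi-square tail probability. Deterministic for fixed input.
#'
#' @inheritParams fit_null
#' @inheritParams kernel_statistic
#' @param a1,a2 Beta weight shape parameters (defaults 1 and 25).
#' @param weights Optional per-variant weights overriding the Beta scheme.
#' @param null Optional pre-fitted `rv_null` for `y`/`covariates` (caching).
#' @param p_method Passed to [quadform_pvalue()].
#' @param p_floor Minimum reportable p-value.
#' @return An object of class `rv_skat` with fields `p_value`, `Q`,
#'   `lambda`, `p_method`, `n_variants`, `n_samples`.
#' @examples
#' set.seed(1)
#' G <- matrix(rbinom(200 * 4, 2, 0.03), 200, 4)
#' y <- rnorm(200) + 0.8 * G[, 1]
#' skat_test(y, G = G)
#' @export
skat_test <- function(y, covariates = NULL, G, a1 = 1, a2 = 25,
                      weights = NULL, null = NULL,
                      p_method = c("auto", "imhof", "moment"),
                      p_floor = 1e-300) {
  p_method <- match.arg(p_method)
  G <- as.matrix(G)
  if (is.null(null)) null <- fit_null(y, covariates)
  maf <- dosage_maf(G)
  if (is.null(weights)) {
    w <- rep(0, ncol(G))
    poly <- maf > 0
    w[poly] <- beta_weights(pmin(maf[poly], 0.5), a1 = a1, a2 = a2)
  } else {
    w <- weights
  }
  ks <- kernel_statistic(null, G, w)
  pv <- quadform_pvalue(ks$Q, ks$lambda, method = p_method, p_floor = p_floor)
  structure(
    list(p_value = pv$p_value, Q = ks$Q, lambda = ks$lambda,
         p_method = pv$method, n_variants = ks$n_variants,
         n_samples = null$n, maf = maf, null = null),
    class = "rv_skat"
  )
}

#' Minor allele frequency from dosages
#'
#' Folded allele frequency per variant column: `min(p, 1 - p)` with
#' `p = mean(dosage) / 2`. Used so that MAF tiers and weights are
#' reproducible from the analyzed sample rather than file metadata.
#'
#' @param G Dosage matrix (samples x variants) or vector.
#' @return Numeric vector of folded MAFs.
#' @export
dosage_maf <- function(G) {
  G <- as.matrix(G)
  p <- colMeans(G, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Permutation p-value for the kernel test
#'
#' Independent resampling oracle: permutes the null-model residuals,
#' recomputes the quadratic form for each permutation and reports
#' \eqn{p = (1 + \#\{Q^{(b)} \ge Q_{obs}\}) / (1 + B)}.
#'
#' @inheritParams skat_test
#' @param n_perm Number of permutations (at least 100).
#' @param seed Integer seed for the permutation stream.
#' @return List with `p_value`, `Q_obs`, `n_perm`.
#' @export
permutation_pvalue <- function(y, covariates = NULL, G, a1 = 1, a2 = 25,
                               weights = NULL, n_perm = 999, seed = 1) {
  if (n_perm < 100) abort("Use at least 100 permutations.")
  G <- as.matrix(G)
  null <- fit_null(y, covariates)
  maf <- dosage_maf(G)
  if (is.null(weights)) {
    w <- rep(0, ncol(G))
    poly <- maf > 0
    w[poly] <- beta_weights(pmin(maf[poly], 0.5), a1 = a1, a2 = a2)
  } else {
    w <- weights
  }
  keep <- apply(G, 2, function(g) var(g) > 0)
  if (!any(keep)) abort("No testable variants.")
  B <- weighted_centered(G[, keep, drop = FALSE], w[keep])
  r <- null$residuals
  q_obs <- sum(as.vector(crossprod(B, r))^2) / (2 * null$sigma2)
  q_perm <- withr::with_seed(seed, {
    idx <- vapply(seq_len(n_perm), function(i) sample.int(null$n),
                  integer(null$n))
    R <- matrix(r[idx], nrow = null$n)
    colSums(crossprod(B, R)^2) / (2 * null$sigma2)
  })
  list(p_value = (1 + sum(q_perm >= q_obs)) / (1 + n_perm),
       Q_obs = q_obs, n_perm = n_perm)
}

#' Single-variant linear regression
#'
#' Per-variant follow-up model: OLS of the trait on one dosage vector plus
#' covariates, reporting the slope, its standard error and the two-sided
#' t-test p-value.
#'
#' @inheritParams fit_null
#' @param g Dosage vector for one variant (must be polymorphic).
#' @return One-row tibble with `beta`, `se`, `p_value`, `df`.
#' @export
single_variant_regression <- function(y, covariates = NULL, g) {
  y <- as.numeric(y)
  g <- as.numeric(g)
  if (var(g) == 0) abort("Variant has zero variance; no regression possible.")
  X <- null_design(covariates, length(y))[, -1, drop = FALSE]
  dat <- data.frame(y = y, g = g)
  if (ncol(X) > 0) {
    fit <- lm(y ~ ., data = cbind(dat, as.data.frame(X)))
  } else {
    fit <- lm(y ~ g, data = dat)
  }
  cf <- summary(fit)$coefficients
  if (anyNA(coef(fit)) || !"g" %in% rownames(cf)) {
    abort("Design including the variant is rank deficient (collinear covariate).")
  }
  tibble(beta = cf["g", "Estimate"], se = cf["g", "Std. Error"],
         p_value = cf["g", "Pr(>|t|)"], df = fit$df.residual)
}

#' @export
print.rv_skat <- function(x, ...) {
  cat("Weighted kernel association test\n")
  cat(sprintf("  variants: %d   samples: %d\n", x$n_variants, x$n_samples))
  cat(sprintf("  Q = %.4g   p = %.4g  (%s)\n", x$Q, x$p_value, x$p_method))
  invisible(x)
}

#' @rdname skat_test
#' @param x An `rv_skat` object.
#' @param ... Unused.
#' @export
tidy.rv_skat <- function(x, ...) {
  tibble(statistic = x$Q, p_value = x$p_value, p_method = x$p_method,
         n_variants = x$n_variants)
}

#' @rdname skat_test
#' @export
glance.rv_skat <- function(x, ...) {
  tibble(n_samples = x$n_samples, n_variants = x$n_variants,
         sigma2 = x$null$sigma2, statistic = x$Q, p_value = x$p_value,
         p_method = x$p_method)
}

#' @export
tidy.rv_null <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @export
glance.rv_null <- function(x, ...) {
  tibble(n = x$n, rank = x$rank, sigma2 = x$sigma2)
}
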