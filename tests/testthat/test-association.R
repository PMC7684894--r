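# The correctness anchors here: the AMLE Wald test must coincide with an
# independently recomputed score test; the offset two-step must reproduce
# OLS exactly in the linear analogue; lr_test is checked against a direct
# likelihood maximization.

test_that("AMLE Wald test equals the independently computed score test", {
  nf <- test_null_fit()
  fit <- nf$fit
  # recompute the projection from Sigma and X with plain solve()
  Si <- solve(fit$sigma)
  P2 <- Si - Si %*% fit$x %*% solve(crossprod(fit$x, Si %*% fit$x),
                                    t(fit$x) %*% Si)
  withr::local_seed(5)
  for (j in sample(ncol(nf$cohort$geno$dosages), 25)) {
    g <- impute_mean_vec(nf$cohort$geno$dosages[, j])
    if (var(g) == 0) next
    a <- amle_test(fit, g)
    u <- sum(g * (nf$y - fit$mu0))
    v <- drop(crossprod(g, P2 %*% g))
    p_score <- pchisq(u^2 / v, df = 1, lower.tail = FALSE)
    expect_lt(abs(a$p - p_score), 1e-12)
    expect_equal(a$score_u, u, tolerance = 1e-10)
    # reciprocal consistency: stat * se^2 = gamma_hat^2
    expect_lt(abs(a$stat * a$se^2 - a$gamma_hat^2), 1e-10)
  }
})

test_that("a genotype orthogonal to the residuals gives a zero AMLE score", {
  nf <- test_null_fit()
  fit <- nf$fit
  r <- nf$y - fit$mu0
  withr::local_seed(8)
  g <- rnorm(length(r))
  g <- g - r * sum(g * r) / sum(r * r)  # project out the residual direction
  a <- amle_test(fit, g)
  expect_equal(a$gamma_hat, 0, tolerance = 1e-10)
  expect_equal(a$stat, 0, tolerance = 1e-12)
  expect_equal(a$p, 1, tolerance = 1e-10)
})

test_that("AMLE agrees with the full PQL refit for small effects", {
  ch <- test_cohort()
  k <- compute_grm(ch$geno)
  x <- cbind(1, compute_pcs(k, 4))
  cfg <- simulation_config(p0 = 0.2, p1 = 0.2, tau = 0.3, gamma = 0.1)
  cand <- which(ch$geno$maf > 0.3)
  diffs <- vapply(1:12, function(r) {
    j <- cand[1 + (r %% length(cand))]
    g <- impute_mean_vec(ch$geno$dosages[, j])
    y <- simulate_phenotype(cfg, ch$Z, k = k, g = g, seed = 1000 + r)
    null <- fit_pql_null(y, x, k)
    a <- amle_test(null, g)$gamma_hat
    b <- fit_pql_snp(y, x, g, k, init = null)$gamma_hat
    abs(a - b)
  }, numeric(1))
  expect_lt(median(diffs), 0.05)
})

test_that("offset two-step reproduces OLS exactly under the identity link", {
  withr::local_seed(13)
  n <- 80
  x <- cbind(1, rnorm(n), runif(n))
  g <- rbinom(n, 2, 0.4)
  y <- drop(x %*% c(1, 0.5, -1)) + 0.3 * g + rnorm(n)
  two_step <- offset_linear_coef(y, x, g)
  full_ols <- qr.solve(cbind(x, g), y)[4]
  expect_lt(abs(two_step - full_ols), 1e-10)
})

test_that("offset residualization leaves X-orthogonal genotypes untouched", {
  nf <- test_null_fit()
  fit <- nf$fit
  withr::local_seed(17)
  g <- rnorm(length(nf$y))
  gt <- g - drop(fit$x %*% qr.solve(fit$x, g))  # orthogonal to X
  delta <- qr.solve(fit$x, gt)
  expect_lt(max(abs(delta)), 1e-10)
  # adding a constant to g changes neither offset nor amle results
  a1 <- offset_test(fit, gt)
  a2 <- offset_test(fit, gt + 1)
  expect_equal(a1$gamma_hat, a2$gamma_hat, tolerance = 1e-6)
  b1 <- amle_test(fit, gt)
  b2 <- amle_test(fit, gt + 1)
  expect_equal(b1$stat, b2$stat, tolerance = 1e-4)
})

test_that("offset p-values are calibrated under the unstructured null", {
  # tau = 0, no strata: the offset test should reject at close to alpha
  withr::local_seed(23)
  n <- 300
  x <- matrix(1, n, 1)
  y <- rbinom(n, 1, 0.3)
  null <- fit_pql_null(y, x, diag(n), fixed_tau = 0)
  m <- 2000
  gs <- matrix(rbinom(n * m, 2, 0.3), n, m)
  ps <- vapply(seq_len(m), function(j) offset_test(null, gs[, j])$p,
               numeric(1))
  rej <- mean(ps < 0.05)
  ci <- 0.05 + c(-1.96, 1.96) * sqrt(0.05 * 0.95 / m)
  expect_gt(rej, ci[1])
  expect_lt(rej, ci[2])
})

test_that("lr_test matches a direct likelihood maximization", {
  # genotype counts: cases (10,20,10), controls (20,20,10)
  g <- c(rep(0, 30), rep(1, 40), rep(2, 20))
  y <- c(rep(1, 10), rep(0, 20), rep(1, 20), rep(0, 20), rep(1, 10), rep(0, 10))
  x <- matrix(1, length(y), 1)
  res <- lr_test(y, x, g)
  nll <- function(b) -sum(y * (b[1] + b[2] * g) - log1p(exp(b[1] + b[2] * g)))
  opt <- optim(c(0, 0), nll, method = "BFGS")
  expect_lt(abs(res$gamma_hat - opt$par[2]), 1e-6)
  expect_error(lr_test(y, cbind(x, g), g), "collinear")
})

test_that("lr_test p-values are uniform under the null", {
  withr::local_seed(29)
  n <- 400; m <- 1500
  x <- matrix(1, n, 1)
  y <- rbinom(n, 1, 0.5)
  ps <- vapply(seq_len(m), function(j) {
    g <- rbinom(n, 2, 0.4)
    lr_test(y, x, g)$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("MLM score test reduces to the linear-regression score when tau = 0", {
  withr::local_seed(37)
  n <- 150
  x <- cbind(1, rnorm(n))
  y <- drop(x %*% c(0.3, 1)) + rnorm(n)
  fit <- fit_lmm_null(y, x, matrix(0, n, n))  # forces tau = 0
  g <- rbinom(n, 2, 0.4)
  res <- mlm_score_test(fit, g)
  # classical OLS score test: U = g'(I-H)y / s2, var = g'(I-H)g / s2
  H <- x %*% solve(crossprod(x), t(x))
  r <- drop((diag(n) - H) %*% y)
  s2 <- fit$sigma2e
  u <- sum(g * r) / s2
  v <- drop(crossprod(g, (diag(n) - H) %*% g)) / s2
  expect_equal(res$stat, u^2 / v, tolerance = 1e-8)
  # orthogonal genotype: zero statistic
  pg <- drop(fit$projection %*% y)
  g0 <- rnorm(n)
  g0 <- g0 - pg * sum(g0 * pg) / sum(pg * pg)
  res0 <- mlm_score_test(fit, g0)
  expect_equal(res0$stat, 0, tolerance = 1e-10)
  expect_equal(res0$p, 1, tolerance = 1e-8)
})

test_that("gwas_scan equals per-SNP calls row for row", {
  nf <- test_null_fit()
  g100 <- nf$cohort$geno[, 1:100]
  tab <- gwas_scan(nf$fit, g100, method = "amle")
  expect_equal(nrow(tab), 100L)
  for (j in c(1, 37, 100)) {
    single <- amle_test(nf$fit, g100$dosages[, j])
    expect_equal(tab$p[j], single$p, tolerance = 1e-15)
    expect_equal(tab$gamma_hat[j], single$gamma_hat, tolerance = 1e-15)
  }
  # failures are recorded, not fatal: make one column constant
  d <- g100$dosages; d[, 7] <- 2
  gbad <- genotype_matrix(d, samples = g100$samples, variants = g100$variants)
  tab2 <- gwas_scan(nf$fit, gbad, method = "amle")
  expect_true(is.na(tab2$p[7]))
  expect_match(tab2$status[7], "constant")
  expect_equal(tab2$p[-7], tab$p[-7], tolerance = 1e-15)
})

test_that("gwas_scan handles empty variant sets and misalignment", {
  nf <- test_null_fit()
  empty <- nf$cohort$geno[, integer(0)]
  tab <- gwas_scan(nf$fit, empty, method = "amle")
  expect_equal(nrow(tab), 0L)
  wrong <- random_genotypes(10, 5, seed = 3)
  expect_error(gwas_scan(nf$fit, wrong, method = "amle"), "sample mismatch")
})
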