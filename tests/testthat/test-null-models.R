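# Oracles: plain logistic regression (stats::glm.fit) for the tau = 0
# reduction; parameter-recovery simulations for the variance component.

test_that("PQL with tau = 0 reduces to plain logistic regression", {
  withr::local_seed(21)
  n <- 200
  x <- cbind(1, rnorm(n), rbinom(n, 1, 0.4))
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * x[, 2]))
  k <- compute_grm(random_genotypes(n, 100, seed = 30))

  glm_fit <- glm.fit(x, y, family = binomial())
  fit0 <- fit_pql_null(y, x, k, fixed_tau = 0)
  expect_lt(max(abs(fit0$beta0 - coef(glm_fit))), 1e-6)
  expect_equal(fit0$omega0, rep(0, n), tolerance = 1e-10)
  expect_equal(fit0$tau, 0)

  # all-zero K behaves identically
  fit00 <- fit_pql_null(y, x, matrix(0, n, n))
  expect_lt(max(abs(fit00$beta0 - coef(glm_fit))), 1e-6)
})

test_that("converged PQL fit satisfies the projection identities", {
  nf <- test_null_fit()
  fit <- nf$fit
  P <- fit$projection
  expect_true(fit$converged)
  expect_gte(fit$tau, 0)
  expect_true(all(fit$mu0 > 0 & fit$mu0 < 1))
  expect_lt(max(abs(P %*% fit$x)) / max(abs(P)), 1e-6)
  expect_lt(max(abs(P - t(P))), 1e-8)
  expect_lt(max(abs(P %*% fit$sigma %*% P - P)), 1e-6)
  # eta0 and mu0 are consistent
  expect_equal(fit$mu0, plogis(fit$eta0), tolerance = 1e-12)
  expect_equal(drop(fit$x %*% fit$beta0) + fit$omega0, fit$eta0,
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("PQL is at a fixed point at convergence", {
  nf <- test_null_fit()
  fit <- nf$fit
  refit <- fit_pql_null(nf$y, nf$x, nf$k, init = fit)
  expect_lt(max(abs(refit$beta0 - fit$beta0)), 5e-6)
  expect_lt(abs(refit$tau - fit$tau), 5e-6)
})

test_that("perfect separation raises a convergence error, not a result", {
  n <- 60
  x <- cbind(1, c(rep(-1, 30), rep(1, 30)))
  y <- c(rep(0, 30), rep(1, 30))
  k <- diag(n)
  expect_error(fit_pql_null(y, x, k), class = "mlrgwas_convergence_error")
})

test_that("input contracts are enforced", {
  n <- 50
  k <- diag(n)
  y <- rep(c(0, 1), 25)
  expect_error(fit_pql_null(rep(1, n), cbind(1, rnorm(n)), k), "constant")
  expect_error(fit_pql_null(y + 0.5, cbind(1, rnorm(n)), k), "0/1")
  x_bad <- cbind(1, 2, rnorm(n))  # rank deficient
  expect_error(fit_pql_null(y, x_bad, k), "rank deficient")
})

test_that("tau estimates increase with the generating tau", {
  # identifiability check: doubling-plus the generating tau (0.3 -> 1)
  # increases the mean estimate across replicates
  n <- 300
  withr::local_seed(77)
  blocks <- matrix(0, n, n)
  for (b in seq_len(n / 10)) {
    idx <- ((b - 1) * 10 + 1):(b * 10)
    blocks[idx, idx] <- 0.5
  }
  diag(blocks) <- 1
  x <- matrix(1, n, 1)
  fac <- mvn_factor(blocks)
  est <- function(tau, seeds) {
    vapply(seeds, function(s) {
      cfg <- simulation_config(p0 = 0.3, p1 = 0.3, tau = tau)
      y <- simulate_phenotype(cfg, rep(0, n), k = fac, seed = s)
      tryCatch(fit_pql_null(y, x, blocks)$tau, error = function(e) NA_real_)
    }, numeric(1))
  }
  t_lo <- est(0.3, 1:25)
  t_hi <- est(1.0, 1:25)
  expect_gt(mean(t_hi, na.rm = TRUE), mean(t_lo, na.rm = TRUE))
})

test_that("full PQL per-SNP fit matches glm in the tau = 0 limit", {
  withr::local_seed(31)
  n <- 150
  x <- cbind(1, rnorm(n))
  g <- rbinom(n, 2, 0.3)
  y <- rbinom(n, 1, plogis(-1 + 0.5 * g))
  res <- fit_pql_snp(y, x, g, diag(n), fixed_tau = 0)
  or_fit <- glm.fit(cbind(x, g), y, family = binomial())
  expect_lt(abs(res$gamma_hat - coef(or_fit)[3]), 1e-6)
  # collinearity is flagged
  expect_error(fit_pql_snp(y, cbind(x, g), g, diag(n)), "collinear")
  expect_error(fit_pql_snp(y, x, rep(1, n), diag(n)), "constant")
})

test_that("LMM REML with k = I matches ordinary least squares", {
  withr::local_seed(41)
  n <- 120
  x <- cbind(1, rnorm(n), runif(n))
  y <- drop(x %*% c(1, 2, -1)) + rnorm(n)
  fit <- fit_lmm_null(y, x, diag(n))
  ols <- qr.solve(x, y)
  expect_lt(max(abs(fit$beta0 - ols)), 1e-6)
  # total variance preserved even though the split is not identified
  s2_ols <- sum((y - drop(x %*% ols))^2) / (n - 3)
  expect_equal(fit$tau + fit$sigma2e, s2_ols, tolerance = 1e-4)
  expect_lt(max(abs(fit$projection %*% x)) / max(abs(fit$projection)), 1e-8)
})

test_that("LMM REML recovers both variance components", {
  withr::local_seed(55)
  n <- 400
  blocks <- matrix(0, n, n)
  for (b in seq_len(n / 8)) {
    idx <- ((b - 1) * 8 + 1):(b * 8)
    blocks[idx, idx] <- 0.9
  }
  diag(blocks) <- 1
  fac <- mvn_factor(blocks)
  x <- cbind(1, rnorm(n))
  taus <- s2s <- numeric(20)
  for (r in 1:20) {
    y <- drop(x %*% c(1, 0.5)) + drop(fac$root %*% rnorm(n)) + rnorm(n)
    f <- fit_lmm_null(y, x, blocks)
    taus[r] <- f$tau; s2s[r] <- f$sigma2e
  }
  expect_gt(mean(taus), 0.6); expect_lt(mean(taus), 1.5)
  expect_gt(mean(s2s), 0.7); expect_lt(mean(s2s), 1.3)
})

test_that("LMM accepts a binary 0/1 status as response", {
  nf <- test_null_fit()
  fit <- fit_lmm_null(nf$y, nf$x, nf$k)
  expect_s3_class(fit, "lmm_null_fit")
  expect_gte(fit$tau, 0)
  expect_gte(fit$sigma2e, 0)
})

test_that("null models can be saved and restored", {
  nf <- test_null_fit()
  path <- withr::local_tempfile(fileext = ".rds")
  save_null_model(nf$fit, path)
  back <- load_null_model(path)
  expect_equal(back$beta0, nf$fit$beta0)
  expect_equal(back$projection, nf$fit$projection)
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(1), bad)
  expect_error(load_null_model(bad), "saved null model")
})
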