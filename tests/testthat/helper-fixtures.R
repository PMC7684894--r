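# Shared fixtures, built in code and cached for the test session.

fixture_env <- new.env(parent = emptyenv())

# Memoise an expensive fixture under a name.
fixture <- function(name, expr) {
  if (!exists(name, fixture_env)) assign(name, force(expr), fixture_env)
  get(name, fixture_env)
}

# Column-mean imputation, re-declared here so tests only rely on exports.
impute_mean_vec <- function(g) {
  if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
  g
}

# A small random genotype matrix with a controlled missing rate.
random_genotypes <- function(n, m, seed = 1, maf = NULL, miss = 0) {
  withr::with_seed(seed, {
    p <- if (is.null(maf)) runif(m, 0.1, 0.9) else rep(maf, m)
    d <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
    if (miss > 0) d[runif(n * m) < miss] <- NA
    genotype_matrix(d)
  })
}

# Structured two-strata cohort shared by the mid-weight tests.
test_cohort <- function() {
  fixture("cohort_small", simulate_cohort(n_snps = 1500, sample_size = 400,
                                          cells_x = 6, cells_y = 6,
                                          founders_per_cell = 9,
                                          couples_per_cell = 2, seed = 99))
}

# Null PQL fit on the shared cohort, with 4 PCs.
test_null_fit <- function() {
  fixture("null_fit_small", {
    ch <- test_cohort()
    k <- compute_grm(ch$geno)
    x <- cbind(1, compute_pcs(k, 4))
    cfg <- simulation_config(p0 = 0.1, p1 = 0.25, tau = 0.5)
    y <- simulate_phenotype(cfg, ch$Z, k = k, seed = 7)
    list(fit = fit_pql_null(y, x, k), y = y, x = x, k = k, cohort = ch)
  })
}
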