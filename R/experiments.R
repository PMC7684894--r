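# Experiment harnesses: type-I error by SNP category, power, and estimator
# bias. Each takes a structured cohort, simulates phenotypes under the
# two-strata mixed model, analyzes them with the requested methods and
# tabulates the results. Everything is deterministic given `seed`.

#' Standard bias-experiment scenarios and MAF bins
#'
#' Scenario A: moderate cohort effect (prevalences 0.10/0.20) and moderate
#' random effect (`tau = 0.3`); B: moderate cohort effect, large random
#' effect (`tau = 1`); C: large cohort effect (0.05/0.30), moderate random
#' effect.
#'
#' @return `default_scenarios()`: a named list of `list(p0, p1, tau)`;
#'   `default_maf_bins()`: a list of `(lo, hi]` intervals.
#' @export
default_scenarios <- function() {
  list(A = list(p0 = 0.10, p1 = 0.20, tau = 0.3),
       B = list(p0 = 0.10, p1 = 0.20, tau = 1),
       C = list(p0 = 0.05, p1 = 0.30, tau = 0.3))
}

#' @rdname default_scenarios
#' @export
default_maf_bins <- function() {
  list(c(0.05, 0.10), c(0.20, 0.25), c(0.45, 0.50))
}

# Covariate matrix: intercept plus top PCs of the analysis GRM.
analysis_covariates <- function(k, n_pcs) {
  n <- nrow(grm_matrix(k))
  if (n_pcs > 0) {
    pcs <- compute_pcs(k, n_pcs)
    cbind(`(Intercept)` = rep(1, n), pcs)
  } else {
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  }
}

maf_bin_candidates <- function(maf, bin) {
  idx <- which(!is.nan(maf) & maf > bin[1] & maf <= bin[2])
  if (length(idx) == 0)
    stop("no variants with MAF in (", bin[1], "; ", bin[2], "]")
  idx
}

#' Type-I error experiment by SNP category
#'
#' Simulates null phenotypes (`gamma = 0`) on a structured two-strata
#' cohort, scans a panel of null SNPs with each requested method, and
#' tabulates rejection rates at level `alpha` within the SNP categories of
#' [snp_categories()]. The phenotype random effect uses the cohort pedigree
#' kinship `K = 2*Phi`, while the analyses use a GRM (and top PCs)
#' estimated from `grm_snps` randomly chosen SNPs -- the deliberate
#' model/analysis mismatch of a realistic GWAS.
#'
#' @param cohort a [simulate_cohort()] result (fields `geno`, `K`, `Z`).
#' @param config a [simulation_config()] with `gamma = 0`.
#' @param methods subset of `"amle"` (the MLR score/Wald test), `"offset"`,
#'   `"lr"`, `"mlm"`.
#' @param n_pcs number of top PCs included as fixed effects.
#' @param n_test_snps number of null SNPs scanned per replicate.
#' @param grm_snps number of SNPs used for the analysis GRM/PCs.
#' @param n_replicates phenotype replicates.
#' @param th category threshold.
#' @param seed integer seed.
#' @return list of class `type1_experiment`: `rates` (method x category
#'   rejection table with binomial 95% CI bounds for the nominal level),
#'   `pvalues` (long table for QQ-plots), `categories`, `config`.
#' @export
run_type1_experiment <- function(cohort, config = simulation_config(),
                                 methods = c("amle", "mlm"),
                                 n_pcs = 10, n_test_snps = 2000,
                                 grm_snps = 2000, n_replicates = 5,
                                 th = 0.8, seed = NULL) {
  stopifnot(inherits(cohort, "cohort"), inherits(config, "simulation_config"))
  if (config$gamma != 0)
    stop("type-I experiment requires gamma = 0 in the configuration")
  methods <- match.arg(methods, c("amle", "offset", "lr", "mlm"),
                       several.ok = TRUE)
  m_all <- nrow(cohort$geno$variants)
  seeds <- derive_seeds(seed, 2 + n_replicates)
  grm_idx <- with_seed(seeds[[1]], sample(m_all, min(grm_snps, m_all)))
  k_grm <- compute_grm(cohort$geno[, grm_idx])
  x <- analysis_covariates(k_grm, n_pcs)
  test_idx <- with_seed(seeds[[2]], sample(m_all, min(n_test_snps, m_all)))
  g_test <- cohort$geno[, test_idx]
  cats <- snp_categories(g_test, cohort$Z, th = th)
  fac <- if (config$tau > 0) mvn_factor(cohort$K) else NULL

  pvals <- list()
  for (r in seq_len(n_replicates)) {
    rs <- derive_seeds(seeds[[2 + r]], 2)
    y <- simulate_phenotype(config, cohort$Z, k = fac, seed = rs[[1]])
    null_pql <- if (any(methods %in% c("amle", "offset")))
      fit_pql_null(y, x, k_grm) else NULL
    null_lmm <- if ("mlm" %in% methods) fit_lmm_null(y, x, k_grm) else NULL
    for (me in methods) {
      null <- switch(me, amle = , offset = null_pql, mlm = null_lmm, lr = y)
      tab <- gwas_scan(null, g_test, method = me, x = x)
      pvals[[length(pvals) + 1L]] <-
        data.frame(replicate = r, method = me, id = tab$id,
                   category = cats$category, p = tab$p,
                   stringsAsFactors = FALSE)
    }
  }
  pvals <- do.call(rbind, pvals)
  rates <- do.call(rbind, lapply(split(pvals, pvals[c("method", "category")],
                                       drop = TRUE),
    function(d) {
      n_ok <- sum(!is.na(d$p))
      data.frame(method = d$method[1], category = d$category[1],
                 n_tests = n_ok, rejections = sum(d$p < config$alpha, na.rm = TRUE),
                 stringsAsFactors = FALSE)
    }))
  rates$rate <- rates$rejections / rates$n_tests
  hw <- 1.96 * sqrt(config$alpha * (1 - config$alpha) / rates$n_tests)
  rates$ci_lo <- config$alpha - hw
  rates$ci_hi <- config$alpha + hw
  rownames(rates) <- NULL
  structure(list(rates = rates, pvalues = pvals, categories = cats,
                 config = config, alpha = config$alpha, th = th),
            class = "type1_experiment")
}

#' Power experiment
#'
#' Per replicate, draws a causal SNP with MAF in `config$maf_bin`,
#' simulates a phenotype with effect `config$gamma`, and tests the causal
#' SNP with each method. Power is the fraction of replicates with
#' `p < config$alpha`; a binomial Monte-Carlo standard error is attached.
#'
#' @inheritParams run_type1_experiment
#' @param methods subset of `"lr"`, `"amle"`, `"offset"`, `"mlm"`.
#' @param grm_from `"all"` uses every cohort SNP for the analysis GRM,
#'   otherwise an integer count of random SNPs.
#' @param use_pedigree_k if `TRUE` (default) the phenotype random effect
#'   uses the pedigree `2*Phi`; otherwise the analysis GRM.
#' @return data frame of class `power_experiment`: `method`, `power`,
#'   `mc_se`, `n_ok`, `n_fail`.
#' @export
run_power_experiment <- function(cohort, config,
                                 methods = c("lr", "amle", "offset"),
                                 n_pcs = 10, grm_from = "all",
                                 use_pedigree_k = TRUE, seed = NULL) {
  stopifnot(inherits(cohort, "cohort"), inherits(config, "simulation_config"))
  if (is.null(config$maf_bin)) stop("config$maf_bin is required")
  methods <- match.arg(methods, c("lr", "amle", "offset", "mlm"),
                       several.ok = TRUE)
  m_all <- nrow(cohort$geno$variants)
  seeds <- derive_seeds(seed, 1 + config$n_replicates)
  k_grm <- if (identical(grm_from, "all")) compute_grm(cohort$geno)
           else compute_grm(cohort$geno[, with_seed(seeds[[1]],
                              sample(m_all, min(grm_from, m_all)))])
  x <- analysis_covariates(k_grm, n_pcs)
  k_pheno <- if (use_pedigree_k) cohort$K else k_grm
  fac <- if (config$tau > 0) mvn_factor(k_pheno) else NULL
  cand <- maf_bin_candidates(cohort$geno$maf, config$maf_bin)

  hits <- setNames(rep(0L, length(methods)), methods)
  n_ok <- setNames(rep(0L, length(methods)), methods)
  last_fit <- NULL
  for (r in seq_len(config$n_replicates)) {
    rs <- derive_seeds(seeds[[1 + r]], 2)
    j <- with_seed(rs[[1]], sample(cand, 1))
    gj <- impute_mean_vec(cohort$geno$dosages[, j])
    y <- simulate_phenotype(config, cohort$Z, k = fac, g = gj, seed = rs[[2]])
    null_pql <- if (any(methods %in% c("amle", "offset")))
      tryCatch(fit_pql_null(y, x, k_grm, init = last_fit),
               error = function(e) NULL) else NULL
    if (!is.null(null_pql)) last_fit <- null_pql
    null_lmm <- if ("mlm" %in% methods)
      tryCatch(fit_lmm_null(y, x, k_grm), error = function(e) NULL) else NULL
    for (me in methods) {
      res <- tryCatch(switch(me,
                             amle = amle_test(null_pql, gj),
                             offset = offset_test(null_pql, gj, x = x),
                             lr = lr_test(y, x, gj),
                             mlm = mlm_score_test(null_lmm, gj)),
                      error = function(e) NULL)
      if (!is.null(res) && is.finite(res$p)) {
        n_ok[me] <- n_ok[me] + 1L
        if (res$p < config$alpha) hits[me] <- hits[me] + 1L
      }
    }
  }
  power <- hits / pmax(n_ok, 1L)
  out <- data.frame(method = methods, power = unname(power),
                    mc_se = unname(sqrt(power * (1 - power) / pmax(n_ok, 1L))),
                    n_ok = unname(n_ok),
                    n_fail = config$n_replicates - unname(n_ok),
                    stringsAsFactors = FALSE)
  class(out) <- c("power_experiment", "data.frame")
  out
}

#' Bias experiment for the SNP-effect estimators
#'
#' For each scenario (prevalences and `tau`) and each causal MAF bin,
#' simulates `n_replicates` phenotypes with SNP effect `gamma` (a new
#' causal SNP and a new random-effect vector each replicate), estimates
#' `gamma` with the requested methods, and reports the mean bias
#' `mean(gamma_hat - gamma)` with its Monte-Carlo standard error.
#'
#' Mirroring a single-panel GWAS design, the phenotype random effect and
#' the analysis both use the GRM computed from all cohort SNPs, with
#' `n_pcs` top PCs as fixed effects.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param gamma causal effect in log-odds units.
#' @param scenarios named list of `list(p0, p1, tau)` (defaults to the
#'   standard A/B/C set).
#' @param maf_bins list of `(lo, hi]` MAF intervals.
#' @param n_replicates replicates per scenario x bin.
#' @param methods subset of `"amle"`, `"offset"`, `"pql"`.
#' @param n_pcs top PCs included as fixed effects.
#' @param seed integer seed.
#' @return data frame of class `bias_experiment`: `scenario`, `maf_lo`,
#'   `maf_hi`, `method`, `gamma`, `mean_bias`, `se`, `n_ok`, `n_fail`.
#' @export
run_bias_experiment <- function(cohort, gamma,
                                scenarios = default_scenarios(),
                                maf_bins = default_maf_bins(),
                                n_replicates = 100,
                                methods = c("amle", "offset", "pql"),
                                n_pcs = 10, seed = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  methods <- match.arg(methods, c("amle", "offset", "pql"), several.ok = TRUE)
  k_grm <- compute_grm(cohort$geno)
  x <- analysis_covariates(k_grm, n_pcs)
  fac <- mvn_factor(k_grm)
  n_cond <- length(scenarios) * length(maf_bins)
  seeds <- derive_seeds(seed, n_cond)
  out <- list()
  ci <- 0L
  for (sc in names(scenarios)) {
    s <- scenarios[[sc]]
    for (bin in maf_bins) {
      ci <- ci + 1L
      cfg <- simulation_config(p0 = s$p0, p1 = s$p1, tau = s$tau,
                               gamma = gamma, maf_bin = bin)
      cand <- maf_bin_candidates(cohort$geno$maf, bin)
      rseeds <- derive_seeds(seeds[[ci]], n_replicates)
      est <- matrix(NA_real_, n_replicates, length(methods),
                    dimnames = list(NULL, methods))
      last_fit <- NULL
      for (r in seq_len(n_replicates)) {
        rs <- derive_seeds(rseeds[[r]], 2)
        j <- with_seed(rs[[1]], sample(cand, 1))
        gj <- impute_mean_vec(cohort$geno$dosages[, j])
        y <- simulate_phenotype(cfg, cohort$Z, k = if (cfg$tau > 0) fac,
                                g = gj, seed = rs[[2]])
        null <- tryCatch(fit_pql_null(y, x, k_grm, init = last_fit),
                         error = function(e) NULL)
        if (is.null(null)) next
        last_fit <- null
        for (me in methods) {
          est[r, me] <- tryCatch(switch(me,
            amle = amle_test(null, gj)$gamma_hat,
            offset = offset_test(null, gj, x = x)$gamma_hat,
            pql = fit_pql_snp(y, x, gj, k_grm, init = null)$gamma_hat),
            error = function(e) NA_real_)
        }
      }
      for (me in methods) {
        ok <- est[, me][is.finite(est[, me])]
        out[[length(out) + 1L]] <- data.frame(
          scenario = sc, maf_lo = bin[1], maf_hi = bin[2], method = me,
          gamma = gamma, mean_bias = mean(ok) - gamma,
          se = sd(ok) / sqrt(length(ok)),
          n_ok = length(ok), n_fail = n_replicates - length(ok),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, out)
  class(out) <- c("bias_experiment", "data.frame")
  out
}
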