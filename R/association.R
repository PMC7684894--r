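# Per-SNP association tests. All of them return a one-row data.frame with
# the AssociationResult fields so gwas_scan() can rbind them.

assoc_row <- function(id = NA_character_, gamma_hat = NA_real_, se = NA_real_,
                      stat = NA_real_, p = NA_real_, method = NA_character_,
                      score_u = NA_real_, status = "ok") {
  # fast-path data.frame construction: this runs once per SNP in a scan
  structure(list(id = id, gamma_hat = gamma_hat, se = se, stat = stat, p = p,
                 method = method, score_u = score_u, status = status),
            class = "data.frame", row.names = c(NA, -1L))
}

#' AMLE test of a single SNP
#'
#' Approximate maximum likelihood estimate of the SNP effect under the
#' mixed logistic regression model, computed from the converged PQL null
#' fit: with residual \eqn{y - \hat\mu_0} and projection `P`,
#' \deqn{U = g'(y-\hat\mu_0),\quad v = g'Pg,\quad
#'   \hat\gamma = U/v,\quad se = 1/\sqrt v,\quad T = U^2/v.}
#' `T` is a Wald statistic for \eqn{\hat\gamma} and at the same time the
#' GMMAT score statistic \eqn{U^2/\mathrm{var}(U)}: the two tests are
#' numerically identical. Cost is one `n x n` mat-vec per SNP, O(n^2).
#'
#' @param null a converged [fit_pql_null()] object.
#' @param g dosage n-vector (missing values mean-imputed).
#' @return one-row data frame: `id`, `gamma_hat` (log-odds), `se`, `stat`
#'   (chi-square 1 df), `p`, `method = "amle"`, `score_u`, `status`.
#' @export
amle_test <- function(null, g) {
  stopifnot(inherits(null, "pql_null_fit"))
  g <- impute_mean_vec(as.numeric(g))
  if (length(g) != length(null$y)) stop("g has wrong length")
  if (var(g) == 0) stop("g is constant: degenerate variant")
  u <- sum(g * (null$y - null$mu0))
  v <- sum(g * drop(null$projection %*% g))
  if (!is.finite(v) || v <= 0) stop("degenerate variant: nonpositive score variance")
  gamma <- u / v
  stat <- u^2 / v
  assoc_row(gamma_hat = gamma, se = 1 / sqrt(v), stat = stat,
            p = chisq1_p(stat), method = "amle", score_u = u)
}

#' Offset test of a single SNP
#'
#' Two-step estimator: (1) residualize the dosages on the covariates,
#' \eqn{\hat\delta = \arg\min \|g - X\delta\|^2},
#' \eqn{\tilde G = g - X\hat\delta}; (2) fit the one-parameter logistic
#' regression \eqn{\mathrm{logit}\,E(Y) = \hat\eta_0 + \tilde G\gamma} by
#' IRLS, the null linear predictor \eqn{\hat\eta_0 = X\hat\beta_0 +
#' \hat\omega_0} being held constant as an offset (no free intercept).
#' Each IRLS iteration is O(n).
#'
#' @param null a converged [fit_pql_null()] object.
#' @param g dosage n-vector.
#' @param x covariate matrix used for residualization (defaults to the
#'   null-model covariates).
#' @param max_iter IRLS iteration cap.
#' @param tol IRLS convergence tolerance on `|dgamma|`.
#' @return one-row data frame with `method = "offset"`.
#' @export
offset_test <- function(null, g, x = NULL, max_iter = 50, tol = 1e-8) {
  stopifnot(inherits(null, "pql_null_fit"))
  g <- impute_mean_vec(as.numeric(g))
  if (length(g) != length(null$y)) stop("g has wrong length")
  if (var(g) == 0) stop("g is constant: degenerate variant")
  x <- if (is.null(x)) null$x else as.matrix(x)
  gt <- stats::.lm.fit(x, g)$residuals
  fit <- offset_logistic(null$y, gt, null$eta0, max_iter = max_iter, tol = tol)
  if (!fit$converged)
    stop(errorCondition("offset IRLS did not converge",
                        class = "mlrgwas_convergence_error"))
  stat <- (fit$gamma / fit$se)^2
  assoc_row(gamma_hat = fit$gamma, se = fit$se, stat = stat,
            p = chisq1_p(stat), method = "offset")
}

# One-parameter logistic IRLS with a fixed offset; O(n) per iteration.
offset_logistic <- function(y, g, offset, max_iter = 50, tol = 1e-8) {
  gamma <- 0
  info <- NA_real_
  for (it in seq_len(max_iter)) {
    mu <- clip_prob(expit(offset + g * gamma))
    wt <- mu * (1 - mu)
    u <- sum(g * (y - mu))
    info <- sum(g * g * wt)
    if (info <= 0) stop("degenerate variant in offset IRLS")
    step <- u / info
    gamma <- gamma + step
    if (abs(step) < tol)
      return(list(gamma = gamma, se = 1 / sqrt(info), converged = TRUE, n_iter = it))
  }
  list(gamma = gamma, se = 1 / sqrt(info), converged = FALSE, n_iter = max_iter)
}

#' Two-step offset estimator in the linear model (identity link)
#'
#' The linear-model analogue of [offset_test()]: ordinary least squares of
#' `y` on `x`, then the slope of the OLS residuals of `g` on the residual
#' response. By Frisch-Waugh-Lovell it equals the multiple-regression OLS
#' coefficient of `g` exactly; exported as the algebraic sanity anchor of
#' the offset heuristic.
#'
#' @param y numeric response.
#' @param x covariate matrix with intercept.
#' @param g dosage vector.
#' @return the scalar estimate of the `g` coefficient.
#' @export
offset_linear_coef <- function(y, x, g) {
  x <- as.matrix(x)
  offset <- drop(x %*% qr.solve(x, y))
  gt <- g - drop(x %*% qr.solve(x, g))
  sum(gt * (y - offset)) / sum(gt * gt)
}

#' Plain logistic regression test of a single SNP
#'
#' Wald test of the SNP coefficient in an ordinary logistic regression on
#' covariates plus dosage (no random effect).
#'
#' @param y binary response.
#' @param x covariate matrix with intercept (typically including top PCs).
#' @param g dosage n-vector.
#' @return one-row data frame with `method = "lr"`.
#' @export
lr_test <- function(y, x, g) {
  y <- as.numeric(y)
  x <- as.matrix(x)
  g <- impute_mean_vec(as.numeric(g))
  if (var(g) == 0) stop("g is constant: degenerate variant")
  xg <- cbind(x, `__snp__` = g)
  if (qr(xg)$rank < ncol(xg)) stop("g is collinear with the covariates")
  fit <- suppressWarnings(glm.fit(xg, y, family = binomial()))
  if (!fit$converged)
    stop(errorCondition("logistic regression did not converge",
                        class = "mlrgwas_convergence_error"))
  mu <- clip_prob(fit$fitted.values)
  wt <- mu * (1 - mu)
  xtwx <- crossprod(xg, xg * wt)
  vc <- solve(xtwx)
  j <- ncol(xg)
  gamma <- unname(coef(fit)[j])
  se <- sqrt(vc[j, j])
  stat <- (gamma / se)^2
  assoc_row(gamma_hat = gamma, se = se, stat = stat, p = chisq1_p(stat),
            method = "lr")
}

#' Mixed linear model score test of a single SNP
#'
#' Score test in the working LMM for the 0/1 status treated as
#' quantitative: \eqn{U = g'P_{lmm}y}, \eqn{\mathrm{var}(U) = g'P_{lmm}g}.
#' The reported effect is on the linear (probability) scale, not log-odds.
#'
#' @param null a [fit_lmm_null()] object.
#' @param g dosage n-vector.
#' @return one-row data frame with `method = "mlm"`.
#' @export
mlm_score_test <- function(null, g) {
  stopifnot(inherits(null, "lmm_null_fit"))
  g <- impute_mean_vec(as.numeric(g))
  if (length(g) != length(null$y)) stop("g has wrong length")
  if (var(g) == 0) stop("g is constant: degenerate variant")
  u <- sum(g * null$py)
  v <- sum(g * drop(null$projection %*% g))
  if (!is.finite(v) || v <= 0) stop("degenerate variant: nonpositive score variance")
  stat <- u^2 / v
  assoc_row(gamma_hat = u / v, se = 1 / sqrt(v), stat = stat,
            p = chisq1_p(stat), method = "mlm", score_u = u)
}

#' Genome-wide association scan
#'
#' Applies one per-SNP method to every variant of a genotype matrix against
#' a fitted null model. Per-variant numerical failures are recorded as `NA`
#' rows with a status message and never abort the scan. No O(n^3) work
#' happens inside the loop: `amle`/`mlm` cost O(n^2) per SNP (one mat-vec
#' against the stored projection), `offset`/`lr` O(n) per IRLS iteration.
#'
#' @param null a `pql_null_fit` (methods `amle`, `offset`, `pql`),
#'   `lmm_null_fit` (method `mlm`), or `NULL` (method `lr`).
#' @param g a [genotype_matrix()].
#' @param method one of `"amle"`, `"offset"`, `"pql"`, `"lr"`, `"mlm"`.
#' @param x covariate matrix, required for `lr` (and used by `offset`/`pql`;
#'   defaults to the null-model covariates).
#' @param k relatedness matrix, required for `pql` only.
#' @return data frame with one row per variant: `chrom`, `pos`, `id`,
#'   `ref`, `alt`, `freq` (alt-allele frequency), `gamma_hat`, `se`,
#'   `stat`, `p`, `method`, `score_u`, `status`.
#' @export
gwas_scan <- function(null, g, method = c("amle", "offset", "pql", "lr", "mlm"),
                      x = NULL, k = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(g, "genotype_matrix"))
  if (method %in% c("amle", "offset", "pql")) {
    if (!inherits(null, "pql_null_fit"))
      stop("method '", method, "' needs a pql_null_fit null model")
  } else if (method == "mlm") {
    if (!inherits(null, "lmm_null_fit"))
      stop("method 'mlm' needs an lmm_null_fit null model")
  }
  y <- NULL
  if (method == "lr" && is.numeric(null)) {
    y <- as.numeric(null)
    null <- NULL
  }
  if (!is.null(null)) {
    if (length(null$y) != length(g$samples))
      stop("sample mismatch: null model has ", length(null$y),
           " samples, genotypes have ", length(g$samples))
    if (!is.null(null$samples) &&
        !identical(as.character(null$samples), g$samples))
      stop("sample mismatch: null model and genotype samples differ in identity or order")
    x <- x %||% null$x
    y <- y %||% null$y
  }
  if (method == "lr" && (is.null(x) || is.null(y)))
    stop("method 'lr' requires a response (y or a null fit) and covariates x")
  if (method == "pql" && is.null(k))
    stop("method 'pql' requires the relatedness matrix k")
  if (!is.null(y) && length(y) != length(g$samples))
    stop("sample mismatch: response has ", length(y),
         " samples, genotypes have ", length(g$samples))

  m <- nrow(g$variants)
  if (m == 0L)
    return(cbind(g$variants[, c("chrom", "pos", "id", "ref", "alt")],
                 freq = numeric(0), assoc_row()[0, -1]))
  freq <- colMeans(g$dosages, na.rm = TRUE) / 2
  rows <- vector("list", m)
  for (j in seq_len(m)) {
    gj <- g$dosages[, j]
    res <- tryCatch(
      switch(method,
             amle = amle_test(null, gj),
             offset = offset_test(null, gj, x = x),
             lr = lr_test(y, x, gj),
             mlm = mlm_score_test(null, gj),
             pql = {
               f <- fit_pql_snp(null$y, x, gj, k, init = null)
               assoc_row(gamma_hat = f$gamma_hat, se = f$se, stat = f$stat,
                         p = f$p, method = "pql")
             }),
      error = function(e) assoc_row(method = method,
                                    status = conditionMessage(e)))
    res$id <- g$variants$id[j]
    rows[[j]] <- res
  }
  out <- do.call(rbind, rows)
  cbind(g$variants[, c("chrom", "pos", "id", "ref", "alt")],
        freq = unname(freq),
        out[, c("gamma_hat", "se", "stat", "p", "method", "score_u", "status")],
        row.names = NULL)
}

#' Write an association table as tab-delimited text
#'
#' @param tab a [gwas_scan()] result.
#' @param path output path; a `.gz` suffix writes a gzip stream.
#' @export
write_association <- function(tab, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(tab, con, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}
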