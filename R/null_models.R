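#' Fit the mixed logistic regression null model by PQL
#'
#' Fits \deqn{\mathrm{logit}\,P(Y=1) = X\beta + \omega,\qquad
#'   \omega \sim MVN(0, \tau K)} by penalized quasi-likelihood: the model is
#' approximated by a sequence of working linear mixed models for the working
#' response \eqn{z = \eta + W^{-1}(y-\mu)} with weights
#' \eqn{W = \mathrm{diag}(\mu(1-\mu))}. Each outer iteration performs a GLS
#' update of \eqn{(\beta,\omega)} and one average-information REML step for
#' \eqn{\tau} (constrained to `tau_range`). Convergence is declared when the
#' largest absolute change in \eqn{(\beta, \tau)} drops below `tol`.
#'
#' The returned object carries everything the fast per-SNP tests need:
#' fitted probabilities \eqn{\hat\mu_0}, the linear predictor
#' \eqn{\hat\eta_0}, the working covariance \eqn{\Sigma = \tau K + W^{-1}},
#' and the projection
#' \eqn{P = \Sigma^{-1} - \Sigma^{-1}X(X'\Sigma^{-1}X)^{-1}X'\Sigma^{-1}},
#' stored dense.
#'
#' @param y binary 0/1 response vector with both classes present.
#' @param x n x p covariate matrix including an intercept column; full rank.
#' @param k relatedness matrix (a [grm()] or bare symmetric matrix).
#' @param tol convergence tolerance on `max(|dbeta|, |dtau|)`.
#' @param max_iter maximum outer iterations.
#' @param tau_init starting value for the variance component.
#' @param tau_range admissible range for `tau`.
#' @param fixed_tau if non-`NULL`, `tau` is held at this value (0 gives a
#'   plain logistic regression with all mixed-model bookkeeping filled in).
#' @param init optional previous fit (`pql_null_fit`) used to warm-start
#'   `beta`/`tau`; coefficients are matched by column name.
#' @param samples optional sample identifiers stored for alignment checks.
#'
#' @return object of class `pql_null_fit`: `beta0`, `vcov_beta`, `omega0`,
#'   `tau`, `mu0`, `eta0`, `w`, `sigma`, `projection`, `converged`,
#'   `n_iter`, plus the inputs `x`, `y` and `samples`.
#' @export
fit_pql_null <- function(y, x, k, tol = 1e-6, max_iter = 200,
                         tau_init = 0.1, tau_range = c(0, 50),
                         fixed_tau = NULL, init = NULL, samples = NULL) {
  y <- as.numeric(y)
  x <- as.matrix(x)
  n <- length(y)
  if (!is_binary(y)) stop("y must be coded 0/1")
  if (length(unique(y)) < 2L) stop("y is constant: both classes must be present")
  if (nrow(x) != n) stop("nrow(x) does not match length(y)")
  if (qr(x)$rank < ncol(x)) stop("covariate matrix x is rank deficient")
  K <- check_square(k, n)
  if (is.null(colnames(x))) colnames(x) <- rep("", ncol(x))
  blank <- colnames(x) == ""
  colnames(x)[blank] <- paste0("x", which(blank))
  samples <- samples %||% grm_samples(k)

  p <- ncol(x)
  zero_k <- all(K == 0)
  tau_fixed <- !is.null(fixed_tau) || zero_k
  tau <- if (!is.null(fixed_tau)) fixed_tau else if (zero_k) 0 else tau_init
  if (tau < 0) stop("tau must be nonnegative")

  # initialization: plain logistic regression for beta, omega = 0
  beta <- if (!is.null(init) && inherits(init, "pql_null_fit")) {
    b <- rep(0, p); names(b) <- colnames(x)
    common <- intersect(names(init$beta0), colnames(x))
    b[common] <- init$beta0[common]
    if (!tau_fixed) tau <- init$tau
    b
  } else {
    g0 <- suppressWarnings(glm.fit(x, y, family = binomial()))
    coef(g0)
  }
  if (anyNA(beta)) stop("initial logistic fit produced NA coefficients")
  eta <- drop(x %*% beta)
  omega <- rep(0, n)

  converged <- FALSE
  iter <- 0L
  XtSiX <- NULL; Si <- NULL; w <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    mu <- clip_prob(expit(eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    Sigma <- tau * K
    diag(Sigma) <- diag(Sigma) + 1 / w
    ch <- tryCatch(chol(Sigma), error = function(e)
      stop(errorCondition(paste0("working covariance not positive definite at iteration ",
                                 iter), class = "mlrgwas_numeric_error")))
    Si <- chol2inv(ch)
    SiXz <- Si %*% cbind(x, z)
    SiX <- SiXz[, seq_len(p), drop = FALSE]
    XtSiX <- crossprod(x, SiX)
    beta_new <- drop(solve(XtSiX, crossprod(x, SiXz[, p + 1L])))
    r <- z - drop(x %*% beta_new)
    Pz <- SiXz[, p + 1L] - drop(SiX %*% beta_new)  # = Si(z - X beta) = Pz
    omega <- tau * drop(K %*% Pz)

    tau_new <- tau
    if (!tau_fixed) {
      KPz <- drop(K %*% Pz)
      # tr(PK) via tr(P Sigma) = n - p and Sigma = tau K + W^{-1}:
      # tr(PK) = (n - p - tr(P W^{-1})) / tau, all terms O(n^2) or less
      trPK <- if (tau > 1e-6) {
        trPWi <- sum(diag(Si) / w) -
          sum(solve(XtSiX) * crossprod(SiX, SiX / w))
        (n - p - trPWi) / tau
      } else {
        M <- crossprod(SiX, K %*% SiX)
        sum(Si * K) - sum(solve(XtSiX) * M)
      }
      score <- -0.5 * (trPK - sum(Pz * KPz))
      SiKPz <- drop(Si %*% KPz)
      PKPz <- SiKPz - drop(SiX %*% solve(XtSiX, crossprod(SiX, KPz)))
      ai <- 0.5 * sum(KPz * PKPz)
      if (is.finite(ai) && ai > 1e-10) {
        tau_new <- tau + score / ai
      } else {
        tau_new <- tau * if (score > 0) 2 else 0.5
      }
      tau_new <- min(max(tau_new, tau_range[1]), tau_range[2])
    }

    delta <- max(abs(beta_new - beta), abs(tau_new - tau))
    beta <- beta_new
    tau <- tau_new
    eta <- drop(x %*% beta) + omega
    if (!is.finite(delta) || max(abs(eta)) > 1e4)
      stop(errorCondition(
        "PQL diverged (linear predictor unbounded); data may be separated",
        class = "mlrgwas_convergence_error",
        last = list(beta = beta, tau = tau, n_iter = iter)))
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop(errorCondition(
      paste0("PQL did not converge in ", max_iter, " iterations"),
      class = "mlrgwas_convergence_error",
      last = list(beta = beta, tau = tau, n_iter = iter)))

  # quantities at the converged point
  mu <- clip_prob(expit(eta))
  w <- mu * (1 - mu)
  z <- eta + (y - mu) / w
  Sigma <- tau * K
  diag(Sigma) <- diag(Sigma) + 1 / w
  Si <- chol2inv(chol(Sigma))
  SiX <- Si %*% x
  XtSiX <- crossprod(x, SiX)
  XtSiX_inv <- solve(XtSiX)
  P <- Si - SiX %*% XtSiX_inv %*% t(SiX)
  P <- (P + t(P)) / 2
  beta <- drop(solve(XtSiX, crossprod(SiX, z)))
  names(beta) <- colnames(x)
  omega <- unname(tau * drop(K %*% (Si %*% (z - drop(x %*% beta)))))
  eta <- unname(drop(x %*% beta) + omega)
  mu <- clip_prob(expit(eta))

  structure(list(beta0 = beta, vcov_beta = XtSiX_inv, omega0 = omega,
                 tau = tau, mu0 = mu, eta0 = eta, w = mu * (1 - mu),
                 sigma = Sigma, projection = P,
                 converged = converged, n_iter = iter,
                 x = x, y = y, samples = samples),
            class = "pql_null_fit")
}

#' @export
print.pql_null_fit <- function(x, ...) {
  cat(sprintf("PQL mixed logistic fit: n = %d, p = %d, tau = %.4f (%s, %d iterations)\n",
              length(x$y), ncol(x$x), x$tau,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Full PQL fit of one SNP (the slow reference estimator)
#'
#' Adds the dosage vector `g` as a fixed effect and refits the whole mixed
#' logistic model by PQL. This is the reference estimator used in bias
#' comparisons; it costs a full O(n^3)-per-iteration fit for every SNP.
#'
#' @inheritParams fit_pql_null
#' @param g dosage n-vector (not constant; missing values mean-imputed).
#' @return list with `gamma_hat`, `se`, `p`, `tau` and the full `fit`.
#' @export
fit_pql_snp <- function(y, x, g, k, ..., init = NULL) {
  g <- impute_mean_vec(as.numeric(g))
  if (var(g) == 0) stop("g is constant: cannot estimate a SNP effect")
  x2 <- cbind(as.matrix(x), `__snp__` = g)
  if (qr(x2)$rank < ncol(x2)) stop("g is collinear with the covariates")
  fit <- fit_pql_null(y, x2, k, ..., init = init)
  j <- ncol(x2)
  gamma <- unname(fit$beta0[j])
  se <- sqrt(fit$vcov_beta[j, j])
  list(gamma_hat = gamma, se = se, stat = (gamma / se)^2,
       p = chisq1_p((gamma / se)^2), tau = fit$tau, fit = fit)
}

#' Fit the linear mixed null model by REML
#'
#' Fits \eqn{y = X\beta + \omega + e}, \eqn{\omega \sim MVN(0,\tau K)},
#' \eqn{e \sim MVN(0, \sigma^2_e I)} by restricted maximum likelihood, using
#' a single eigendecomposition of `K` and a 1-D profiled-likelihood search
#' over the heritability ratio. Used as the (deliberately misspecified for
#' binary traits) MLM comparator, the 0/1 status being treated as
#' quantitative.
#'
#' @param y numeric response (may be a 0/1 status).
#' @param x covariate matrix with intercept, full rank.
#' @param k relatedness matrix.
#' @param samples optional sample identifiers.
#' @return object of class `lmm_null_fit`: `beta0`, `omega0`, `tau`,
#'   `sigma2e`, `projection`, `py`, `converged`, `x`, `y`, `samples`.
#' @export
fit_lmm_null <- function(y, x, k, samples = NULL) {
  y <- as.numeric(y)
  x <- as.matrix(x)
  n <- length(y)
  if (nrow(x) != n) stop("nrow(x) does not match length(y)")
  if (qr(x)$rank < ncol(x)) stop("covariate matrix x is rank deficient")
  K <- check_square(k, n)
  samples <- samples %||% grm_samples(k)
  p <- ncol(x)

  e <- eigen(K, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  yt <- drop(crossprod(e$vectors, y))
  xt <- crossprod(e$vectors, x)

  # REML log-likelihood profiled over total variance, h = tau / (tau + s2e)
  reml_nll <- function(h) {
    d <- h * lam + (1 - h)
    xd <- xt / d
    xtdx <- crossprod(xt, xd)
    bh <- solve(xtdx, crossprod(xd, yt))
    r <- yt - drop(xt %*% bh)
    v <- sum(r^2 / d) / (n - p)
    0.5 * ((n - p) * log(v) + sum(log(d)) +
             determinant(xtdx, logarithm = TRUE)$modulus)
  }
  opt <- optimize(reml_nll, interval = c(0, 1 - 1e-8))
  # guard the boundaries, which optimize() never evaluates exactly
  h <- opt$minimum
  if (reml_nll(1e-10) <= opt$objective) h <- 0
  d <- h * lam + (1 - h)
  xd <- xt / d
  xtdx <- crossprod(xt, xd)
  beta <- drop(solve(xtdx, crossprod(xd, yt)))
  r <- yt - drop(xt %*% beta)
  v <- sum(r^2 / d) / (n - p)
  tau <- v * h
  s2e <- v * (1 - h)
  names(beta) <- colnames(x) %||% paste0("x", seq_len(p))

  Sigma <- tau * K
  diag(Sigma) <- diag(Sigma) + s2e
  Si <- chol2inv(chol(Sigma))
  SiX <- Si %*% x
  XtSiX <- crossprod(x, SiX)
  P <- Si - SiX %*% solve(XtSiX) %*% t(SiX)
  P <- (P + t(P)) / 2
  omega <- tau * drop(K %*% (Si %*% (y - drop(x %*% beta))))

  structure(list(beta0 = beta, omega0 = omega, tau = tau, sigma2e = s2e,
                 projection = P, py = drop(P %*% y), converged = TRUE,
                 x = x, y = y, samples = samples),
            class = "lmm_null_fit")
}

#' @export
print.lmm_null_fit <- function(x, ...) {
  cat(sprintf("REML linear mixed fit: n = %d, tau = %.4f, sigma2e = %.4f\n",
              length(x$y), x$tau, x$sigma2e))
  invisible(x)
}

#' Save / restore a fitted null model
#'
#' Serializes the fit so a genome scan can resume without refitting.
#'
#' @param fit a `pql_null_fit` or `lmm_null_fit`.
#' @param path file path.
#' @export
save_null_model <- function(fit, path) {
  stopifnot(inherits(fit, c("pql_null_fit", "lmm_null_fit")))
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_null_model
#' @export
load_null_model <- function(path) {
  fit <- readRDS(path)
  if (!inherits(fit, c("pql_null_fit", "lmm_null_fit")))
    stop("'", path, "' does not contain a saved null model")
  fit
}
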