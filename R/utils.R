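# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All user-facing stochastic operations funnel through this.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# Derive a stream of sub-seeds from a master seed; keeps every derived
# seed a valid 32-bit integer.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

logit <- function(p) qlogis(p)
expit <- function(x) plogis(x)

# Clip probabilities away from 0/1 so binomial weights stay invertible.
clip_prob <- function(p, eps = 1e-8) pmin(pmax(p, eps), 1 - eps)

is_binary <- function(y) all(y %in% c(0, 1))

# Extract the plain relatedness matrix from a `grm` object or a bare matrix.
grm_matrix <- function(k) {
  if (inherits(k, "grm")) k$matrix else as.matrix(k)
}

grm_samples <- function(k) {
  if (inherits(k, "grm")) k$samples else rownames(as.matrix(k))
}

check_square <- function(k, n, what = "k") {
  m <- grm_matrix(k)
  if (nrow(m) != ncol(m)) stop(sprintf("'%s' must be a square matrix", what))
  if (!is.null(n) && nrow(m) != n)
    stop(sprintf("'%s' has dimension %d, expected %d", what, nrow(m), n))
  invisible(m)
}

# Column-mean imputation of missing dosages; columns that are entirely
# missing are imputed to 0.
impute_mean <- function(x) {
  if (!anyNA(x)) return(x)
  mu <- colMeans(x, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(x), arr.ind = TRUE)
  x[idx] <- mu[idx[, 2L]]
  x
}

impute_mean_vec <- function(g) {
  if (!anyNA(g)) return(g)
  m <- mean(g, na.rm = TRUE)
  if (is.nan(m)) m <- 0
  g[is.na(g)] <- m
  g
}

# chi-square(1) upper-tail p-value, the convention used by every test here.
chisq1_p <- function(stat) pchisq(stat, df = 1, lower.tail = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
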