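#' Genomic relationship matrix container
#'
#' @param matrix n x n symmetric relatedness matrix.
#' @param samples sample identifiers aligned with rows/columns.
#' @param source one of `"genotype"`, `"pedigree"`, `"user"`.
#' @return object of class `grm` with fields `matrix`, `samples`, `source`.
#' @export
grm <- function(matrix, samples = NULL, source = c("user", "genotype", "pedigree")) {
  source <- match.arg(source)
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != ncol(matrix)) stop("GRM must be square")
  if (max(abs(matrix - t(matrix))) > 1e-10)
    stop("GRM must be symmetric (tolerance 1e-10)")
  if (is.null(samples)) samples <- rownames(matrix) %||% paste0("S", seq_len(nrow(matrix)))
  samples <- as.character(samples)
  if (length(samples) != nrow(matrix))
    stop("length(samples) does not match GRM dimension")
  dimnames(matrix) <- list(samples, samples)
  structure(list(matrix = matrix, samples = samples, source = source),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d samples, source = %s, mean diagonal %.3f\n",
              length(x$samples), x$source, mean(diag(x$matrix))))
  invisible(x)
}

#' Genomic relationship matrix from genotypes
#'
#' Computes the standard VanRaden-type GRM
#' \deqn{K_{ij} = \frac{1}{m}\sum_s \frac{(g_{is}-2p_s)(g_{js}-2p_s)}{2p_s(1-p_s)}}
#' where \eqn{p_s} is the sample alternate-allele frequency of variant `s`.
#' Missing dosages are mean-imputed per column first; monomorphic columns are
#' excluded from the sum and from `m`. Allele frequencies are estimated from
#' the full sample.
#'
#' @param g a [genotype_matrix()].
#' @return a [grm()] with `source = "genotype"`.
#' @export
compute_grm <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  x <- impute_mean(g$dosages)
  p <- colMeans(x) / 2
  poly <- p > 0 & p < 1 & (colMeans(x^2) - (2 * p)^2) > 0
  if (!any(poly))
    stop("cannot compute a GRM: no polymorphic variants")
  x <- x[, poly, drop = FALSE]
  p <- p[poly]
  z <- sweep(x, 2L, 2 * p, "-")
  z <- sweep(z, 2L, sqrt(2 * p * (1 - p)), "/")
  k <- tcrossprod(z) / ncol(z)
  k <- (k + t(k)) / 2
  grm(k, samples = g$samples, source = "genotype")
}

#' Principal components of a relationship matrix
#'
#' Returns the unit-norm eigenvectors of the GRM for its largest
#' eigenvalues, ordered by decreasing eigenvalue, with the sign of each
#' component fixed so its largest-magnitude loading is positive. These are
#' the coordinates used as fixed-effect covariates ("top PCs") in the
#' association models.
#'
#' @param k a [grm()] or bare symmetric matrix.
#' @param n_components number of components, `1 <= n_components <= n`.
#' @return an `n x n_components` matrix with attribute `"values"` holding
#'   the corresponding eigenvalues.
#' @export
compute_pcs <- function(k, n_components) {
  m <- grm_matrix(k)
  n <- nrow(m)
  if (!is.numeric(n_components) || length(n_components) != 1L ||
      n_components < 1 || n_components > n)
    stop("n_components must be between 1 and ", n)
  n_components <- as.integer(n_components)
  e <- eigen(m, symmetric = TRUE)
  v <- e$vectors[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(ncol(v))) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  rownames(v) <- grm_samples(k)
  colnames(v) <- paste0("PC", seq_len(n_components))
  attr(v, "values") <- e$values[seq_len(n_components)]
  v
}

#' Write / read a GRM as a delimited square matrix with sample IDs
#'
#' @param k a [grm()].
#' @param path output file.
#' @export
write_grm <- function(k, path) {
  stopifnot(inherits(k, "grm"))
  write.table(format(k$matrix, digits = 17, trim = TRUE, scientific = TRUE),
              path, quote = FALSE, sep = "\t",
              row.names = k$samples, col.names = k$samples)
  invisible(path)
}

#' @rdname write_grm
#' @param source source tag recorded on the object read back.
#' @export
read_grm <- function(path, source = "user") {
  m <- as.matrix(read.table(path, header = TRUE, sep = "\t",
                            row.names = 1, check.names = FALSE))
  grm(m, samples = rownames(m), source = source)
}
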