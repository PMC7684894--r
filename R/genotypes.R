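#' Genotype matrix container
#'
#' Holds an `n x m` dosage matrix (counts of the alternate allele, coded
#' 0/1/2, `NA` for missing) together with sample identifiers, per-variant
#' metadata, and the per-variant minor allele frequency.
#'
#' @param dosages numeric matrix, individuals in rows, variants in columns;
#'   entries must be 0, 1, 2 or `NA`.
#' @param samples character vector of sample identifiers (defaults to
#'   rownames or `S1..Sn`).
#' @param variants data frame with columns `chrom`, `pos`, `id`, `ref`,
#'   `alt` (defaults are generated).
#'
#' @return An object of class `genotype_matrix` with fields `dosages`,
#'   `samples`, `variants` and `maf`.
#' @export
genotype_matrix <- function(dosages, samples = NULL, variants = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  bad <- !is.na(dosages) & !(dosages %in% c(0, 1, 2))
  if (any(bad))
    stop("dosages must be 0, 1, 2 or NA (alt-allele counts); first offending value: ",
         dosages[which(bad)[1L]])
  n <- nrow(dosages); m <- ncol(dosages)
  if (is.null(samples)) samples <- rownames(dosages) %||% paste0("S", seq_len(n))
  samples <- as.character(samples)
  if (length(samples) != n)
    stop("length(samples) [", length(samples), "] does not match nrow(dosages) [", n, "]")
  if (is.null(variants)) {
    ids <- colnames(dosages) %||% paste0("snp", seq_len(m))
    variants <- data.frame(chrom = rep("1", m), pos = seq_len(m), id = ids,
                           ref = rep("A", m), alt = rep("B", m),
                           stringsAsFactors = FALSE)
  }
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(need %in% names(variants)))
    stop("variants must have columns: ", paste(need, collapse = ", "))
  if (nrow(variants) != m)
    stop("nrow(variants) [", nrow(variants), "] does not match ncol(dosages) [", m, "]")
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  variants$id <- as.character(variants$id)
  rownames(variants) <- NULL
  dimnames(dosages) <- list(samples, variants$id)
  structure(list(dosages = dosages, samples = samples,
                 variants = variants[, need], maf = compute_maf(dosages)),
            class = "genotype_matrix")
}

#' Minor allele frequencies of a dosage matrix
#'
#' @param dosages numeric matrix of 0/1/2 dosages (`NA` allowed).
#' @return per-column minor allele frequency in `[0, 0.5]`; `NaN` for
#'   all-missing columns.
#' @export
compute_maf <- function(dosages) {
  p <- colMeans(dosages, na.rm = TRUE) / 2
  unname(pmin(p, 1 - p))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants\n",
              length(x$samples), nrow(x$variants)))
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing rate %.3f, median MAF %.3f\n",
              miss, median(x$maf, na.rm = TRUE)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix
#'
#' @param x a [genotype_matrix()].
#' @param i sample (row) index.
#' @param j variant (column) index.
#' @param ... ignored.
#' @return a `genotype_matrix` restricted to the requested samples/variants.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$samples)
  if (missing(j)) j <- seq_len(nrow(x$variants))
  genotype_matrix(x$dosages[i, j, drop = FALSE],
                  samples = x$samples[i],
                  variants = x$variants[j, , drop = FALSE])
}

#' Filter variants on minor allele frequency
#'
#' Keeps the variants whose minor allele frequency is at least `threshold`
#' (the boundary is kept); column order is preserved. The usual GWAS
#' pre-processing step of discarding variants below, e.g., 5% MAF.
#'
#' @param g a [genotype_matrix()].
#' @param threshold MAF threshold in `[0, 0.5]`.
#' @return a `genotype_matrix` with the retained columns (possibly none).
#' @export
filter_maf <- function(g, threshold) {
  stopifnot(inherits(g, "genotype_matrix"),
            is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 0.5)
  keep <- which(!is.nan(g$maf) & g$maf >= threshold)
  g[, keep]
}
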