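#' Stratifying variable for QQ diagnostics
#'
#' A vector `z` with components in `[0, 1]`: either the 0/1 indicator of a
#' known population stratum, or a continuous proxy such as a top genomic PC
#' rescaled to `[0, 1]`.
#'
#' @param z numeric n-vector in `[0, 1]`, not all equal.
#' @param kind `"indicator"` or `"continuous"` (guessed if missing).
#' @return object of class `strata_vector`.
#' @export
strata_vector <- function(z, kind = NULL) {
  z <- as.numeric(z)
  if (any(!is.finite(z)) || any(z < 0) || any(z > 1))
    stop("z components must lie in [0, 1]")
  if (length(unique(z)) < 2L) stop("z must not be constant")
  if (is.null(kind)) kind <- if (all(z %in% c(0, 1))) "indicator" else "continuous"
  kind <- match.arg(kind, c("indicator", "continuous"))
  structure(list(z = z, kind = kind), class = "strata_vector")
}

#' Rescale a principal component to a stratifying variable
#'
#' Min-max rescales a PC coordinate vector to `[0, 1]` for use as a
#' continuous stratifying variable when the population strata are unknown.
#'
#' @param pc numeric vector (e.g. one column of [compute_pcs()]).
#' @return a `strata_vector` of kind `"continuous"`.
#' @export
pc_strata <- function(pc) {
  pc <- as.numeric(pc)
  rng <- range(pc)
  if (diff(rng) == 0) stop("PC is constant: cannot rescale to [0, 1]")
  strata_vector((pc - rng[1]) / diff(rng), kind = "continuous")
}

#' Categorize SNPs by the between-strata genotype-variance ratio
#'
#' For each SNP, the alternate-allele frequency attributed to each stratum
#' is \deqn{q_1 = \frac{Z'G}{2\,Z'\mathbf 1},\qquad
#'   q_0 = \frac{(\mathbf 1-Z)'G}{2\,(\mathbf 1-Z)'\mathbf 1},} the expected
#' genotype variances under panmixia are \eqn{var_i = 2p_iq_i} with
#' \eqn{p_i = 1-q_i}, and the ratio \eqn{r = var_1/var_0} assigns category
#' 1 (`r < th`), 2 (`th <= r <= 1/th`, boundaries inclusive) or 3
#' (`r > 1/th`). With a 0/1 indicator `z` the `q_i` are exactly the
#' within-stratum allele frequencies. SNPs monomorphic in stratum 0 are
#' category 3 when `var_1 > 0` and unassigned (`NA`) when both variances
#' vanish.
#'
#' @param g a [genotype_matrix()] (missing dosages mean-imputed).
#' @param z a [strata_vector()] or numeric vector in `[0, 1]`.
#' @param th variance-ratio threshold in `(0, 1)`; 0.8 is the conventional
#'   choice.
#' @return data frame of class `snp_categories`: `id`, `q0`, `q1`, `r`,
#'   `category` (integer 1/2/3 or `NA`), with attribute `"th"`.
#' @export
snp_categories <- function(g, z, th = 0.8) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!inherits(z, "strata_vector")) z <- strata_vector(z)
  if (!is.numeric(th) || length(th) != 1L || th <= 0 || th >= 1)
    stop("th must lie strictly between 0 and 1")
  zz <- z$z
  if (length(zz) != length(g$samples))
    stop("z has length ", length(zz), ", expected ", length(g$samples))
  s1 <- sum(zz); s0 <- sum(1 - zz)
  if (s1 == 0 || s0 == 0) stop("degenerate strata: one stratum has zero total weight")
  G <- impute_mean(g$dosages)
  q1 <- drop(crossprod(zz, G)) / (2 * s1)
  q0 <- drop(crossprod(1 - zz, G)) / (2 * s0)
  v1 <- 2 * q1 * (1 - q1)
  v0 <- 2 * q0 * (1 - q0)
  r <- ifelse(v0 > 0, v1 / v0, ifelse(v1 > 0, Inf, NA_real_))
  category <- ifelse(is.na(r), NA_integer_,
                     ifelse(r < th, 1L, ifelse(r <= 1 / th, 2L, 3L)))
  out <- data.frame(id = g$variants$id, q0 = unname(q0), q1 = unname(q1),
                    r = unname(r), category = unname(category),
                    stringsAsFactors = FALSE)
  attr(out, "th") <- th
  class(out) <- c("snp_categories", "data.frame")
  out
}

#' Stratified QQ-plot table
#'
#' Computes, per SNP category and pooled (`"all"`), the observed sorted
#' \eqn{-\log_{10} p} against the uniform expectation
#' \eqn{-\log_{10} i/(n_c+1)}. Rendering is separate ([plot_stratified_qq()])
#' so the computation runs headless.
#'
#' @param pvalues per-SNP p-values in `(0, 1]`.
#' @param categories a [snp_categories()] result (or an integer vector of
#'   categories) aligned with `pvalues`.
#' @return data frame with columns `category` (`"1"`, `"2"`, `"3"`,
#'   `"all"`), `expected`, `observed` (both `-log10` scale).
#' @export
stratified_qq <- function(pvalues, categories) {
  p <- as.numeric(pvalues)
  if (length(p) == 0 || any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("pvalues must lie in (0, 1]")
  cat_vec <- if (inherits(categories, "snp_categories")) categories$category
             else as.integer(categories)
  if (length(cat_vec) != length(p))
    stop("categories and pvalues are not aligned")
  groups <- c(stats::setNames(lapply(1:3, function(k) p[!is.na(cat_vec) & cat_vec == k]),
                              c("1", "2", "3")),
              list(all = p))
  out <- lapply(names(groups), function(nm) {
    pk <- groups[[nm]]
    nk <- length(pk)
    if (nk == 0) {
      warning("category ", nm, " is empty and was omitted")
      return(NULL)
    }
    data.frame(category = nm,
               expected = -log10(seq_len(nk) / (nk + 1)),
               observed = sort(-log10(pk), decreasing = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Render a stratified QQ-plot
#'
#' @param tbl a [stratified_qq()] table.
#' @param main plot title.
#' @param col colors for categories 1, 2, 3 and pooled.
#' @export
plot_stratified_qq <- function(tbl, main = "Stratified QQ-plot",
                               col = c(`1` = "#1b9e77", `2` = "#7570b3",
                                       `3` = "#d95f02", all = "grey30")) {
  lim <- c(0, max(tbl$expected, tbl$observed))
  graphics::plot(NA, xlim = lim, ylim = lim,
                 xlab = expression(Expected ~ -log[10](p)),
                 ylab = expression(Observed ~ -log[10](p)), main = main)
  graphics::abline(0, 1, lty = 2, col = "grey60")
  for (nm in unique(tbl$category)) {
    sub <- tbl[tbl$category == nm, ]
    graphics::points(sub$expected, sub$observed, pch = 20, cex = 0.5,
                     col = col[[nm]])
  }
  graphics::legend("topleft", legend = unique(tbl$category), col =
                     col[unique(tbl$category)], pch = 20, bty = "n")
  invisible(tbl)
}

#' Genomic inflation factor
#'
#' Median-based genomic control: each p-value is converted to its
#' chi-square(1) upper-tail equivalent and
#' \deqn{\lambda = \mathrm{median}(\chi^2) / 0.4549364...} (the median of
#' the null chi-square(1) distribution).
#'
#' @param pvalues p-values in `(0, 1]`.
#' @return the scalar inflation factor.
#' @export
genomic_inflation <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (length(p) == 0) stop("pvalues is empty")
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("pvalues must lie in (0, 1]")
  stats::median(qchisq(p, df = 1, lower.tail = FALSE)) /
    qchisq(0.5, df = 1, lower.tail = FALSE)
}
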