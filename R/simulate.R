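# Synthetic structured cohorts: a spatial Balding-Nichols-style generator on
# a grid of demes (large-scale allele-frequency gradients plus local deme
# noise on the logit scale), gene-dropped first-degree relatives, and the
# two-strata binary phenotype model used throughout the experiments.

# Default logit-scale structure intensity, calibrated once so that splitting
# the default 20x20 grid into two equal halves gives Hudson F_ST ~ 0.007
# (< 0.01, comparable to within-Europe differentiation).
GRID_STRUCTURE_DEFAULT <- 0.3

#' Simulate founder genotypes on a structured grid
#'
#' Each SNP draws an ancestral allele frequency from
#' `uniform(freq_range)`. Per-cell frequencies deviate from it on the logit
#' scale by a unit-variance spatial field -- a random large-scale gradient
#' across the grid plus independent per-cell noise, mixed with weight
#' `spatial_share` -- scaled by `structure_param`. Founder genotypes are
#' `Binomial(2, p_cell)`. `structure_param = 0` gives a panmictic
#' population; the default is calibrated so that a half-grid split shows
#' F_ST below 0.01.
#'
#' @param cells_x,cells_y grid dimensions.
#' @param founders_per_cell founders simulated in every cell.
#' @param n_snps number of independent SNPs.
#' @param structure_param logit-scale standard deviation of the spatial
#'   field (>= 0).
#' @param seed integer seed; the output is deterministic given the seed.
#' @param freq_range ancestral allele-frequency spectrum.
#' @param spatial_share share of the field variance carried by the
#'   large-scale gradient (the rest is per-cell noise).
#' @return object of class `grid_population`: `geno` (a
#'   [genotype_matrix()] of the founders), `cell` (cell index per founder),
#'   `cells` (per-cell grid coordinates), the grid dimensions, and the
#'   generator parameters.
#' @export
simulate_grid_genotypes <- function(cells_x = 20, cells_y = 20,
                                    founders_per_cell = 20, n_snps = 1000,
                                    structure_param = GRID_STRUCTURE_DEFAULT,
                                    seed = NULL,
                                    freq_range = c(0.05, 0.95),
                                    spatial_share = 0.5) {
  if (cells_x < 1 || cells_y < 1 || founders_per_cell < 1 || n_snps < 1)
    stop("grid dimensions, founders_per_cell and n_snps must be positive")
  if (structure_param < 0) stop("structure_param must be nonnegative")
  n_cells <- cells_x * cells_y
  cells <- expand.grid(x = seq_len(cells_x), y = seq_len(cells_y))
  xs <- if (cells_x > 1) scale(cells$x)[, 1] else rep(0, n_cells)
  ys <- if (cells_y > 1) scale(cells$y)[, 1] else rep(0, n_cells)
  with_seed(seed, {
    p_anc <- runif(n_snps, freq_range[1], freq_range[2])
    theta <- runif(n_snps, 0, 2 * pi)
    # unit-variance spatial field per SNP: gradient + local deme noise
    grad <- outer(xs, cos(theta)) + outer(ys, sin(theta))  # n_cells x n_snps
    noise <- matrix(rnorm(n_cells * n_snps), n_cells, n_snps)
    field <- sqrt(spatial_share) * grad + sqrt(1 - spatial_share) * noise
    lp <- sweep(structure_param * field, 2L, logit(p_anc), "+")
    p_cell <- expit(lp)
    cell <- rep(seq_len(n_cells), each = founders_per_cell)
    n <- length(cell)
    dos <- matrix(rbinom(n * n_snps, 2L, p_cell[cell, ]), n, n_snps)
    geno <- genotype_matrix(dos, samples = paste0("F", seq_len(n)))
    structure(list(geno = geno, cell = cell, cells = cells,
                   cells_x = cells_x, cells_y = cells_y,
                   founders_per_cell = founders_per_cell,
                   structure_param = structure_param,
                   spatial_share = spatial_share, seed = seed),
              class = "grid_population")
  })
}

#' @export
print.grid_population <- function(x, ...) {
  cat(sprintf("grid_population: %dx%d grid, %d founders/cell, %d SNPs, structure %.3f\n",
              x$cells_x, x$cells_y, x$founders_per_cell,
              nrow(x$geno$variants), x$structure_param))
  invisible(x)
}

#' Wright's fixation index between two groups
#'
#' Hudson estimator, as a ratio of averages over SNPs:
#' \deqn{F_{ST} = \frac{\sum_s (p_{1s}-p_{2s})^2 - h_{1s}/(n_1-1) -
#'   h_{2s}/(n_2-1)}{\sum_s p_{1s}(1-p_{2s}) + p_{2s}(1-p_{1s})}}
#' with \eqn{h_{is} = p_{is}(1-p_{is})}.
#'
#' @param g a [genotype_matrix()] or dosage matrix.
#' @param groups two-level grouping vector aligned with the samples.
#' @return the scalar F_ST estimate.
#' @export
compute_fst <- function(g, groups) {
  dos <- if (inherits(g, "genotype_matrix")) g$dosages else as.matrix(g)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("groups must have exactly two levels")
  i1 <- groups == levels(groups)[1]
  n1 <- sum(i1); n2 <- sum(!i1)
  if (n1 < 2 || n2 < 2) stop("each group needs at least two individuals")
  p1 <- colMeans(dos[i1, , drop = FALSE], na.rm = TRUE) / 2
  p2 <- colMeans(dos[!i1, , drop = FALSE], na.rm = TRUE) / 2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (2 * n1 - 1) - p2 * (1 - p2) / (2 * n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  keep <- is.finite(num) & is.finite(den) & den > 0
  sum(num[keep]) / sum(den[keep])
}

#' Half-grid F_ST of a grid population
#'
#' Splits the grid into two equal halves along the x axis and computes
#' [compute_fst()] between them; the structure calibration target.
#'
#' @param pop a [simulate_grid_genotypes()] result.
#' @return the scalar F_ST estimate.
#' @export
half_grid_fst <- function(pop) {
  stopifnot(inherits(pop, "grid_population"))
  half <- pop$cells$x[pop$cell] <= pop$cells_x / 2
  compute_fst(pop$geno, half)
}

#' Gene-drop offspring on a grid population
#'
#' Forms `couples_per_cell` disjoint founder couples in every cell,
#' simulates `offspring_per_couple` offspring per couple by gene dropping
#' (each offspring allele drawn uniformly and independently from the
#' parent's two alleles at every SNP), computes the pedigree kinship matrix
#' \eqn{\Phi}, and samples `sample_size` individuals uniformly without
#' replacement from founders plus offspring.
#'
#' @param pop a [simulate_grid_genotypes()] result.
#' @param couples_per_cell founder couples formed per cell.
#' @param offspring_per_couple offspring per couple (0 keeps only founders).
#' @param sample_size cohort size drawn from founders + offspring
#'   (default: everyone).
#' @param seed integer seed.
#' @return list of class `pedigree_sample`: `geno` (a
#'   [genotype_matrix()]), `phi` (kinship matrix of the sample), `kinship2`
#'   (a [grm()] holding `K = 2*Phi`, source `"pedigree"`), `cell`,
#'   `is_founder`, and `pedigree` (parent indices per sampled individual).
#' @export
gene_drop <- function(pop, couples_per_cell = 10, offspring_per_couple = 2,
                      sample_size = NULL, seed = NULL) {
  stopifnot(inherits(pop, "grid_population"))
  fpc <- pop$founders_per_cell
  if (couples_per_cell * 2 > fpc)
    stop("not enough founders per cell for ", couples_per_cell, " couples")
  n_cells <- pop$cells_x * pop$cells_y
  nf <- length(pop$geno$samples)
  dosf <- pop$geno$dosages
  with_seed(seed, {
    father <- integer(0); mother <- integer(0); off_cell <- integer(0)
    for (cc in seq_len(n_cells)) {
      ids <- which(pop$cell == cc)
      pairs <- matrix(sample(ids, 2 * couples_per_cell), nrow = 2)
      father <- c(father, rep(pairs[1, ], each = offspring_per_couple))
      mother <- c(mother, rep(pairs[2, ], each = offspring_per_couple))
      off_cell <- c(off_cell, rep(cc, couples_per_cell * offspring_per_couple))
    }
    no <- length(father)
    if (no > 0) {
      m <- ncol(dosf)
      transmit <- function(par) {
        pr <- dosf[par, , drop = FALSE] / 2
        matrix(rbinom(no * m, 1L, pr), no, m)
      }
      doso <- transmit(father) + transmit(mother)
    } else doso <- matrix(0, 0, ncol(dosf))
    dos <- rbind(dosf, doso)
    total <- nf + no
    cell_all <- c(pop$cell, off_cell)
    is_founder <- c(rep(TRUE, nf), rep(FALSE, no))
    ped_f <- c(rep(NA_integer_, nf), father)
    ped_m <- c(rep(NA_integer_, nf), mother)

    sample_size <- sample_size %||% total
    if (sample_size > total)
      stop("sample_size (", sample_size, ") exceeds population size (", total, ")")
    keep <- sort(sample(total, sample_size))

    # kinship of founders + one gene-dropped generation, founders unrelated
    # and non-inbred: phi(i,i) = 1/2; phi(offspring, parent) = 1/4;
    # full sibs (same couple) 1/4; half sibs (one shared parent) 1/8.
    phi <- matrix(0, total, total)
    if (no > 0) {
      oi <- nf + seq_len(no)
      # offspring-offspring: 1/8 per shared parent (1/4 for full sibs)
      shared <- outer(father, father, "==") + outer(mother, mother, "==")
      phi[oi, oi] <- 0.125 * shared
      # offspring-parent: 1/4
      po <- cbind(rep(oi, 2L), c(father, mother))
      phi[po] <- 0.25
      phi[po[, 2:1]] <- 0.25
    }
    diag(phi) <- 0.5
    phi_s <- phi[keep, keep]
    ids <- ifelse(is_founder, paste0("F", seq_len(total)),
                  paste0("O", seq_len(total) - nf))[keep]
    geno <- genotype_matrix(dos[keep, , drop = FALSE], samples = ids,
                            variants = pop$geno$variants)
    dimnames(phi_s) <- list(ids, ids)
    structure(list(geno = geno, phi = phi_s,
                   kinship2 = grm(2 * phi_s, samples = ids, source = "pedigree"),
                   cell = cell_all[keep], is_founder = is_founder[keep],
                   pedigree = data.frame(id = ids, father = ped_f[keep],
                                         mother = ped_m[keep]),
                   cells = pop$cells, cells_x = pop$cells_x,
                   cells_y = pop$cells_y, seed = seed),
              class = "pedigree_sample")
  })
}

#' Two-strata structured cohort
#'
#' Convenience wrapper: grid founders, gene-dropped offspring, uniform
#' sampling, and the high-risk stratum indicator (`Z = 1` for individuals
#' whose cell lies in the top-left quarter of the grid).
#'
#' @inheritParams simulate_grid_genotypes
#' @inheritParams gene_drop
#' @return list of class `cohort`: `geno`, `K` (pedigree `2*Phi` [grm()]),
#'   `phi`, `Z` (stratum indicator), `cell`, `is_founder`.
#' @export
simulate_cohort <- function(cells_x = 10, cells_y = 10, founders_per_cell = 8,
                            n_snps = 2000,
                            structure_param = GRID_STRUCTURE_DEFAULT,
                            couples_per_cell = 2, offspring_per_couple = 2,
                            sample_size = 800, seed = NULL,
                            spatial_share = 0.5) {
  seeds <- derive_seeds(seed, 2)
  pop <- simulate_grid_genotypes(cells_x, cells_y, founders_per_cell, n_snps,
                                 structure_param, seed = seeds[[1]],
                                 spatial_share = spatial_share)
  ped <- gene_drop(pop, couples_per_cell, offspring_per_couple,
                   sample_size, seed = seeds[[2]])
  zz <- as.numeric(ped$cells$x[ped$cell] <= cells_x / 2 &
                     ped$cells$y[ped$cell] <= cells_y / 2)
  structure(list(geno = ped$geno, K = ped$kinship2, phi = ped$phi,
                 Z = zz, cell = ped$cell, is_founder = ped$is_founder,
                 cells_x = cells_x, cells_y = cells_y, seed = seed),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d individuals (%d in high-risk stratum), %d SNPs, %dx%d grid\n",
              length(x$geno$samples), sum(x$Z), nrow(x$geno$variants),
              x$cells_x, x$cells_y))
  invisible(x)
}

#' Simulation configuration
#'
#' Stores the two-strata phenotype-model parameters: stratum prevalences
#' `p0`, `p1` (converted to `a0 = logit(p0)` and
#' `a1 = logit(p1) - logit(p0)`), variance component `tau`, SNP effect
#' `gamma` (log-odds), causal MAF bin, replicate count, significance level
#' and seed.
#'
#' @param p0,p1 prevalences in the low- and high-risk stratum.
#' @param tau random-effect variance (>= 0).
#' @param gamma SNP effect in log-odds units (0 under the null).
#' @param maf_bin numeric length-2 half-open interval `(lo, hi]` from which
#'   causal SNPs are drawn, or `NULL`.
#' @param n_replicates number of simulation replicates.
#' @param alpha significance threshold.
#' @param seed integer seed.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(p0 = 0.05, p1 = 0.30, tau = 1, gamma = 0,
                              maf_bin = NULL, n_replicates = 100,
                              alpha = 0.05, seed = NULL) {
  stopifnot(p0 > 0, p0 < 1, p1 > 0, p1 < 1, tau >= 0)
  structure(list(p0 = p0, p1 = p1, a0 = logit(p0), a1 = logit(p1) - logit(p0),
                 tau = tau, gamma = gamma, maf_bin = maf_bin,
                 n_replicates = n_replicates, alpha = alpha, seed = seed),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("simulation_config: p0 = %.3f, p1 = %.3f (a0 = %.3f, a1 = %.3f), tau = %.2f, gamma = %.3f\n",
              x$p0, x$p1, x$a0, x$a1, x$tau, x$gamma))
  invisible(x)
}

#' Read a simulation configuration from a key = value text file
#'
#' Lines of the form `key = value`; `#` starts a comment. Recognized keys:
#' `p0`, `p1`, `tau`, `gamma`, `maf_lo`, `maf_hi`, `n_replicates`, `alpha`,
#' `seed`. Unknown keys raise an error; omitted keys keep the
#' [simulation_config()] defaults.
#'
#' @param path configuration file path.
#' @return a [simulation_config()].
#' @export
read_simulation_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- sub("#.*$", "", readLines(path))
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: '", lines[bad][1L], "'")
  vals <- setNames(vapply(kv, function(p) as.numeric(p[2]), numeric(1)),
                   vapply(kv, `[`, character(1), 1))
  if (anyNA(vals)) stop("non-numeric value for key '",
                        names(vals)[is.na(vals)][1L], "'")
  known <- c("p0", "p1", "tau", "gamma", "maf_lo", "maf_hi",
             "n_replicates", "alpha", "seed")
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown configuration key(s): ",
                            paste(unknown, collapse = ", "))
  args <- as.list(vals[intersect(names(vals), setdiff(known, c("maf_lo", "maf_hi")))])
  if (all(c("maf_lo", "maf_hi") %in% names(vals)))
    args$maf_bin <- c(vals[["maf_lo"]], vals[["maf_hi"]])
  else if (any(c("maf_lo", "maf_hi") %in% names(vals)))
    stop("maf_lo and maf_hi must be given together")
  do.call(simulation_config, args)
}

#' Precompute the MVN factor of a relatedness matrix
#'
#' Symmetric eigendecomposition with eigenvalues floored at zero, used to
#' draw `omega ~ MVN(0, tau*K)` repeatedly. An error is raised when `K` has
#' an eigenvalue below `-1e-8` (relative to the largest).
#'
#' @param k a [grm()] or matrix.
#' @return object of class `mvn_factor`.
#' @export
mvn_factor <- function(k) {
  m <- grm_matrix(k)
  e <- eigen(m, symmetric = TRUE)
  tol <- 1e-8 * max(1, abs(e$values[1]))
  if (min(e$values) < -tol)
    stop("relatedness matrix is not positive semi-definite (min eigenvalue ",
         format(min(e$values)), ")")
  structure(list(root = e$vectors %*% diag(sqrt(pmax(e$values, 0)),
                                           nrow(m)),
                 n = nrow(m)),
            class = "mvn_factor")
}

#' Simulate a binary phenotype under the two-strata mixed model
#'
#' Draws \deqn{y_i \sim \mathrm{Bernoulli}\big(\mathrm{logit}^{-1}(a_0 +
#'   a_1 z_i + \gamma \tilde g_i + \omega_i)\big),\qquad
#'   \omega \sim MVN(0, \tau K),} where \eqn{\tilde g} is the causal dosage
#' vector centered so the expected prevalences stay as prescribed.
#'
#' @param config a [simulation_config()].
#' @param z stratum variable (a [strata_vector()] or numeric in `[0, 1]`).
#' @param k relatedness matrix, [grm()] or precomputed [mvn_factor()];
#'   may be `NULL` when `tau = 0`.
#' @param g optional causal dosage vector (centered internally).
#' @param seed integer seed.
#' @return binary 0/1 n-vector.
#' @export
simulate_phenotype <- function(config, z, k = NULL, g = NULL, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  zz <- if (inherits(z, "strata_vector")) z$z else as.numeric(z)
  n <- length(zz)
  eta <- config$a0 + config$a1 * zz
  if (!is.null(g)) {
    g <- as.numeric(g)
    if (length(g) != n) stop("g has wrong length")
    eta <- eta + config$gamma * (g - mean(g))
  }
  with_seed(seed, {
    if (config$tau > 0) {
      if (is.null(k)) stop("k is required when tau > 0")
      fac <- if (inherits(k, "mvn_factor")) k else mvn_factor(k)
      if (fac$n != n) stop("k dimension does not match z")
      eta <- eta + sqrt(config$tau) * drop(fac$root %*% rnorm(n))
    }
    rbinom(n, 1L, expit(eta))
  })
}
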