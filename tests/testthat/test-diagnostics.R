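test_that("snp_categories matches the hand-computed example", {
  # Z = (1,1,0,0), G = (2,1,0,1): q1 = 0.75, q0 = 0.25, var1 = var0 = 0.375
  g <- genotype_matrix(matrix(c(2, 1, 0, 1), 4, 1))
  res <- snp_categories(g, c(1, 1, 0, 0), th = 0.8)
  expect_equal(res$q1, 0.75)
  expect_equal(res$q0, 0.25)
  expect_equal(res$r, 1)
  expect_equal(res$category, 2L)
})

test_that("binary strata give within-stratum allele frequencies", {
  g <- random_genotypes(50, 40, seed = 12)
  z <- rep(c(0, 1), each = 25)
  res <- snp_categories(g, z)
  expect_equal(res$q1, colMeans(g$dosages[z == 1, ]) / 2, ignore_attr = TRUE)
  expect_equal(res$q0, colMeans(g$dosages[z == 0, ]) / 2, ignore_attr = TRUE)
})

test_that("category boundaries are inclusive for category 2", {
  # with q1 = 0.5, q0 = 0.25: var1 = 0.5, var0 = 0.375, r = 4/3;
  # th = 0.75 puts r exactly on the upper boundary 1/th -> category 2
  g <- genotype_matrix(matrix(c(1, 1, 1, 0), 4, 1))
  res <- snp_categories(g, c(1, 1, 0, 0), th = 0.75)
  expect_equal(res$r, 4 / 3, tolerance = 1e-12)
  expect_equal(res$category, 2L)
  # just inside th = 0.76: 1/th < 4/3 -> category 3
  res3 <- snp_categories(g, c(1, 1, 0, 0), th = 0.76)
  expect_equal(res3$category, 3L)
  # lower boundary: relabel strata so r = 3/4 = th exactly -> category 2
  res_lo <- snp_categories(g, c(0, 0, 1, 1), th = 0.75)
  expect_equal(res_lo$r, 3 / 4, tolerance = 1e-12)
  expect_equal(res_lo$category, 2L)
  expect_error(snp_categories(g, c(1, 1, 0, 0), th = 1), "strictly between")
})

test_that("strata relabeling swaps categories 1 and 3", {
  ch <- test_cohort()
  g <- ch$geno[, 1:400]
  a <- snp_categories(g, ch$Z)
  b <- snp_categories(g, 1 - ch$Z)
  expect_equal(b$r, 1 / a$r, tolerance = 1e-10)
  swap <- c(`1` = 3L, `2` = 2L, `3` = 1L)
  expect_equal(b$category, unname(swap[as.character(a$category)]))
})

test_that("monomorphic-in-one-stratum SNPs follow the documented rule", {
  # monomorphic in stratum 0, polymorphic in stratum 1 -> category 3
  g1 <- genotype_matrix(cbind(c(1, 1, 0, 0), c(0, 0, 0, 0)))
  res <- snp_categories(g1, c(1, 1, 0, 0))
  expect_equal(res$category[1], 3L)   # var0 = 0, var1 > 0
  expect_true(is.na(res$category[2])) # both variances zero -> excluded
  expect_error(snp_categories(g1, c(0, 0, 0, 0)), "not be constant")
})

test_that("continuous-Z (PC) categories agree with binary strata on a
           strongly clustered cohort", {
  # two strongly differentiated demes with gene-dropped relatives
  two <- fixture("cohort_two_cluster", {
    pop <- simulate_grid_genotypes(cells_x = 2, cells_y = 1,
                                   founders_per_cell = 120, n_snps = 1200,
                                   structure_param = 1.5,
                                   spatial_share = 0.85, seed = 3)
    ped <- gene_drop(pop, couples_per_cell = 25, offspring_per_couple = 2,
                     sample_size = 300, seed = 4)
    list(geno = ped$geno, Z = as.numeric(ped$cell == 1))
  })
  k <- compute_grm(two$geno)
  z_pc <- pc_strata(compute_pcs(k, 1)[, 1])
  a <- snp_categories(two$geno, two$Z)
  b <- snp_categories(two$geno, z_pc)
  # PC1 may be anti-aligned with the stratum indicator; accept either
  b_flip <- snp_categories(two$geno, 1 - z_pc$z)
  agree <- max(mean(a$category == b$category, na.rm = TRUE),
               mean(a$category == b_flip$category, na.rm = TRUE))
  expect_gte(agree, 0.8)
})

test_that("stratified_qq reproduces exact uniform quantiles on the diagonal", {
  n <- 200
  p <- (1:n) / (n + 1)
  tbl <- suppressWarnings(stratified_qq(p, rep(1L, n)))
  one <- tbl[tbl$category == "1", ]
  expect_equal(one$observed, one$expected, tolerance = 1e-12)
  # dividing all p-values by 10 shifts the observed curve up by exactly 1
  tbl2 <- suppressWarnings(stratified_qq(p / 10, rep(1L, n)))
  expect_equal(tbl2[tbl2$category == "1", "observed"],
               one$observed + 1, tolerance = 1e-12)
  # pooled curve is always present
  expect_true("all" %in% tbl$category)
})

test_that("empty categories are omitted with a warning", {
  p <- runif(50, 0.01, 1)
  warns <- character(0)
  tbl <- withCallingHandlers(stratified_qq(p, rep(2L, 50)),
                             warning = function(w) {
                               warns <<- c(warns, conditionMessage(w))
                               invokeRestart("muffleWarning")
                             })
  expect_length(warns, 2L)  # categories 1 and 3 are empty
  expect_match(warns, "empty", all = TRUE)
  expect_setequal(unique(tbl$category), c("2", "all"))
  expect_error(stratified_qq(c(0.5, 0), rep(1L, 2)), "0, 1")
})

test_that("genomic inflation factor is calibrated", {
  n <- 1001
  p <- (1:n) / (n + 1)
  expect_equal(genomic_inflation(p), 1, tolerance = 1e-6)
  # doubling the chi-square statistics doubles lambda
  stats <- qchisq(p, 1, lower.tail = FALSE)
  p2 <- pchisq(2 * stats, 1, lower.tail = FALSE)
  expect_equal(genomic_inflation(p2), 2 * genomic_inflation(p),
               tolerance = 1e-6)
  expect_equal(genomic_inflation(0.5), 1, tolerance = 1e-12)
  expect_error(genomic_inflation(numeric(0)), "empty")
})

test_that("plot_stratified_qq renders headless", {
  p <- runif(100, 0.001, 1)
  tbl <- stratified_qq(p, sample(1:3, 100, replace = TRUE))
  path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(path)
  expect_silent(plot_stratified_qq(tbl))
  grDevices::dev.off()
  expect_true(file.size(path) > 0)
})
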