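test_that("standardization follows the binomial convention", {
  d <- make_dataset(cbind(c(0, 1, 2, 1)))
  z <- standardize(d)
  expect_equal(unname(z$Z[, 1]), c(-sqrt(2), 0, sqrt(2), 0))
  # missing entries become exactly 0; frequencies use non-missing calls
  d2 <- make_dataset(cbind(c(0, 1, NA, 1)))
  z2 <- standardize(d2)
  p <- 1 / 3
  expect_equal(z2$freqs[[1]], p)
  expect_equal(unname(z2$Z[, 1]),
               c((0 - 2 * p), (1 - 2 * p), 0, (1 - 2 * p)) /
                 c(rep(sqrt(2 * p * (1 - p)), 2), 1, sqrt(2 * p * (1 - p))))
  # all-het column: p = 0.5, z all zero, kept and flagged
  d3 <- make_dataset(cbind(c(1, 1, 1, 1), c(0, 1, 2, 0)))
  z3 <- standardize(d3)
  expect_true(z3$zero_variance[1])
  expect_equal(unname(z3$Z[, 1]), rep(0, 4))
  # monomorphic column errors, naming the variant
  d4 <- make_dataset(cbind(c(2, 2, 2, 2)))
  expect_error(standardize(d4), "monomorphic")
})

test_that("PCA matches an explicit covariance eigendecomposition", {
  set.seed(8)
  for (dims in list(c(20, 40), c(30, 12))) {
    d <- make_dataset(matrix(sample(0:2, prod(dims), replace = TRUE,
                                    prob = c(.4, .4, .2)),
                             nrow = dims[1]))
    st <- compute_variant_stats(d)
    d <- subset_variants(d, which(st$maf > 0))
    z <- standardize(d)
    k <- 5
    pc <- compute_pcs(z, k)
    C <- tcrossprod(z$Z) / ncol(z$Z)
    ev <- eigen(C, symmetric = TRUE)
    expect_equal(pc$eigenvalues, ev$values[1:k], tolerance = 1e-8)
    # scores span the same subspace with the documented scaling
    for (i in 1:k) {
      expect_equal(abs(cor(pc$scores[, i], ev$vectors[, i])), 1,
                   tolerance = 1e-6)
      expect_equal(sum(pc$scores[, i]^2), nrow(z$Z) * pc$eigenvalues[i],
                   tolerance = 1e-8)
    }
  }
})

test_that("eigenvalue sum equals the trace of the scaled covariance", {
  set.seed(9)
  d <- make_dataset(matrix(sample(0:2, 25 * 30, replace = TRUE), nrow = 25))
  z <- standardize(d)
  pc <- compute_pcs(z, 24)
  expect_equal(sum(pc$eigenvalues), sum(diag(tcrossprod(z$Z) / ncol(z$Z))),
               tolerance = 1e-8)
})

test_that("rank deficiency and sample duplication behave as expected", {
  set.seed(10)
  base <- matrix(sample(0:2, 2 * 30, replace = TRUE), nrow = 2)
  d <- make_dataset(base[c(1, 2, 1, 2, 1, 2), ])
  st <- compute_variant_stats(d)
  d <- subset_variants(d, which(st$maf > 0))
  pc <- compute_pcs(standardize(d), 3)
  # two distinct duplicated rows -> rank <= 2 (after centering effectively 1)
  expect_lte(pc$eigenvalues[3], 1e-10 * pc$eigenvalues[1])

  dd <- make_dataset(matrix(sample(0:2, 10 * 40, replace = TRUE), nrow = 10))
  std <- compute_variant_stats(dd)
  dd <- subset_variants(dd, which(std$maf > 0))
  dup <- genotype_dataset(dd$variants, c(dd$samples, paste0(dd$samples, "b")),
                          rbind(dd$dosage, dd$dosage))
  p1 <- compute_pcs(standardize(dd), 4)
  p2 <- compute_pcs(standardize(dup), 4)
  expect_equal(p1$eigenvalues / p1$eigenvalues[1],
               p2$eigenvalues / p2$eigenvalues[1], tolerance = 1e-8)
})

test_that("PCA sign convention and repeat runs are bit-stable", {
  set.seed(11)
  d <- make_dataset(matrix(sample(0:2, 20 * 50, replace = TRUE), nrow = 20))
  st <- compute_variant_stats(d)
  d <- subset_variants(d, which(st$maf > 0))
  pc1 <- compute_pcs(standardize(d), 5)
  pc2 <- compute_pcs(standardize(d), 5)
  expect_identical(pc1$scores, pc2$scores)
  for (i in 1:5) {
    expect_gt(pc1$loadings[which.max(abs(pc1$loadings[, i])), i], 0)
  }
  # invariant to variant order (scores unchanged)
  perm <- sample(n_variants(d))
  pc3 <- compute_pcs(standardize(subset_variants(d, perm)), 5)
  expect_equal(pc3$eigenvalues, pc1$eigenvalues, tolerance = 1e-8)
  expect_equal(unname(abs(diag(cor(pc3$scores, pc1$scores)))), rep(1, 5),
               tolerance = 1e-8)
})

test_that("score columns are orthogonal", {
  set.seed(12)
  d <- make_dataset(matrix(sample(0:2, 30 * 80, replace = TRUE), nrow = 30))
  st <- compute_variant_stats(d)
  d <- subset_variants(d, which(st$maf > 0))
  pc <- compute_pcs(standardize(d), 6)
  g <- crossprod(pc$scores) / nrow(pc$scores)
  off <- abs(g[upper.tri(g)])
  expect_lt(max(off) / max(diag(g)), 1e-8)
})

test_that("PC1 separates two Balding-Nichols populations", {
  sim <- simulate_genotypes(k_pops = 2, fst = 0.1, n_per_pop = 50,
                            n_variants = 2000, seed = 13)
  st <- compute_variant_stats(sim$data)
  d <- subset_variants(sim$data, which(st$maf > 0.05))
  pc <- compute_pcs(standardize(d), 2)
  lab <- as.integer(sim$labels)
  expect_gt(abs(cor(pc$scores[, 1], lab)), 0.9)
})

test_that("GRM identities hold", {
  # single variant, dosages 0 and 2: GRM = [[2,-2],[-2,2]]
  d <- make_dataset(cbind(c(0L, 2L)))
  g <- compute_grm(standardize(d))
  expect_equal(unname(g$matrix), matrix(c(2, -2, -2, 2), 2), tolerance = 1e-12)
  # duplicate samples: off-diagonal equals the diagonals
  set.seed(14)
  dd <- make_dataset(rbind(v1 <- sample(0:2, 60, replace = TRUE), v1,
                           sample(0:2, 60, replace = TRUE)))
  st <- compute_variant_stats(dd)
  dd <- subset_variants(dd, which(st$maf > 0))
  g2 <- compute_grm(standardize(dd))
  expect_equal(g2$matrix[1, 2], g2$matrix[1, 1], tolerance = 1e-10)
  expect_equal(g2$matrix[1, 2], g2$matrix[2, 2], tolerance = 1e-10)
  expect_true(isSymmetric(g2$matrix, tol = 1e-10))
  # mean diagonal approaches 1 at large m under no structure
  sim <- simulate_genotypes(k_pops = 1, fst = 0, n_per_pop = 60,
                            n_variants = 5000, seed = 15)
  sts <- compute_variant_stats(sim$data)
  ds <- subset_variants(sim$data, which(sts$maf > 0))
  g3 <- compute_grm(standardize(ds))
  expect_lt(abs(mean(diag(g3$matrix)) - 1), 0.05)
  expect_gt(min(eigen(g3$matrix, symmetric = TRUE, only.values = TRUE)$values),
            -1e-8 * sum(diag(g3$matrix)) / nrow(g3$matrix))
})

test_that("joint PCA merges, harmonizes and labels cohorts", {
  sim <- simulate_genotypes(k_pops = 3, fst = 0.1, n_per_pop = 20,
                            n_variants = 800, seed = 16)
  st <- compute_variant_stats(sim$data)
  d <- subset_variants(sim$data, which(st$maf > 0.05))
  # A = B: merged PCs equal single-cohort PCs on doubled samples
  jp <- joint_pca(d, d, k = 3)
  dup <- genotype_dataset(d$variants, c(d$samples, paste0(d$samples, "_dup")),
                          rbind(d$dosage, d$dosage))
  ref <- compute_pcs(standardize(dup), 3)
  expect_equal(jp$pc$eigenvalues, ref$eigenvalues, tolerance = 1e-8)
  expect_equal(jp$cohort, rep(c("A", "B"), each = n_samples(d)))
  expect_equal(jp$n_overlap, n_variants(d))
  # strand-complemented copy gives the identical result
  b <- d
  b$variants$ref <- complement_alleles(d$variants$ref)
  b$variants$alt <- complement_alleles(d$variants$alt)
  jp2 <- joint_pca(d, b, k = 3)
  expect_equal(jp2$pc$eigenvalues, jp$pc$eigenvalues, tolerance = 1e-10)
  expect_equal(jp2$pc$scores, jp$pc$scores, tolerance = 1e-10)
  # three populations split across two files separate in PC1/PC2
  half <- seq_len(n_samples(d)) %% 2 == 0
  ja <- subset_samples(d, which(half))
  jb <- subset_samples(d, which(!half))
  jp3 <- joint_pca(ja, jb, k = 2)
  lab <- sim$labels[match(sub("_dup.*", "", jp3$pc$samples),
                          sim$data$samples)]
  sc <- jp3$pc$scores
  sil <- cluster_silhouette(sc, as.integer(lab))
  expect_gt(sil, 0.5)
})
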