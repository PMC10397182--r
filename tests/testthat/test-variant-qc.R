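test_that("variant statistics arithmetic on non-missing calls", {
  d <- make_dataset(cbind(c(0, 0, 1, NA), c(2, 2, 2, 2), c(0, 1, NA, 1)))
  st <- compute_variant_stats(d)
  # first column over its 3 calls: alt freq 1/6
  expect_equal(st$alt_freq[1], 1 / 6)
  expect_equal(st$maf[1], 1 / 6)
  expect_equal(st$call_rate[1], 0.75)
  expect_true(st$monomorphic[2])
  expect_equal(st$maf[2], 0)
  expect_equal(st$call_rate[3], 0.75)
  expect_equal(st$alt_freq[3], 2 / 6)
})

test_that("HWE exact test matches full enumeration to 1e-12", {
  expect_equal(hwe_exact_test(0, 0, 100), 1)
  expect_equal(hwe_exact_test(5, 0, 5), hwe_enum_oracle(5, 0, 5),
               tolerance = 1e-12)
  expect_equal(hwe_exact_test(1, 2, 1), hwe_enum_oracle(1, 2, 1),
               tolerance = 1e-12)
  expect_error(hwe_exact_test(-1, 2, 1), "negative")
  worst <- 0
  for (a in 0:16) for (b in 0:16) for (c in 0:16) {
    if (a + b + c >= 1 && a + b + c <= 16) {
      worst <- max(worst, abs(hwe_exact_test(a, b, c) - hwe_enum_oracle(a, b, c)))
    }
  }
  expect_lt(worst, 1e-12)
  # spot checks at larger totals (up to 50 genotypes)
  for (cfg in list(c(20, 10, 20), c(45, 4, 1), c(10, 30, 10), c(0, 50, 0))) {
    expect_equal(hwe_exact_test(cfg[1], cfg[2], cfg[3]),
                 hwe_enum_oracle(cfg[1], cfg[2], cfg[3]), tolerance = 1e-12)
  }
})

test_that("variant filters apply in order with conservation of counts", {
  d <- make_dataset(
    matrix(rep(c(0, 1, 2, 1), 8), nrow = 4),
    chrom = c("X", "1", "1", "1", "6", "1", "1", "1"),
    pos = c(100L, 200L, 200L, 300L, 29000000L, 400L, 500L, 600L),
    ref = c("A", "A", "A", "A", "A", "A", "A", "A"),
    alt = c("G", "G", "G", "T", "G", "G", "G", "G")
  )
  # variant 6 made rare (maf <= 0.05 boundary handled below), variant 7 missing-heavy
  d$dosage[, 6] <- c(0, 0, 0, 0)       # monomorphic -> maf rule
  d$dosage[, 7] <- c(NA, NA, 1, 0)     # call rate 0.5 < 0.9
  fv <- filter_variants(d)
  expect_equal(unname(fv$removed["non_autosomal"]), 1L)
  expect_equal(unname(fv$removed["duplicate"]), 1L)
  expect_equal(unname(fv$removed["palindromic"]), 1L)
  expect_equal(unname(fv$removed["excluded_region"]), 1L)
  expect_equal(unname(fv$removed["call_rate"]), 1L)
  expect_equal(unname(fv$removed["maf"]), 1L)
  expect_equal(sum(fv$removed) + fv$kept, n_variants(d))
  # idempotence
  fv2 <- filter_variants(fv$data)
  expect_equal(fv2$kept, fv$kept)
  expect_equal(sum(fv2$removed), 0L)
})

test_that("MAF boundary is strict: maf equal to the threshold is removed", {
  # 10 samples, 1 het -> alt freq 0.05 exactly
  d <- make_dataset(matrix(c(1, rep(0, 9), rep(c(0, 1), 5)), nrow = 10))
  fv <- filter_variants(d, th = qc_thresholds(maf_min = 0.05))
  expect_equal(unname(fv$removed["maf"]), 1L)
  expect_equal(fv$kept, 1L)
})

test_that("sample missingness filter keeps a sample at exactly the limit", {
  dos <- matrix(0L, nrow = 3, ncol = 10)
  dos[1, 1:3] <- NA   # 30% missing -> removed
  dos[2, 1:2] <- NA   # exactly 20% -> kept ("more than 20%")
  d <- make_dataset(dos)
  fs <- filter_samples(d, mind_max = 0.2)
  expect_equal(fs$removed, "S1")
  expect_equal(fs$data$samples, c("S2", "S3"))
  # no missing data: identity
  d2 <- make_dataset(matrix(1L, 2, 4))
  expect_equal(filter_samples(d2)$data$samples, d2$samples)
  # all removed: explicit empty-cohort error
  d3 <- make_dataset(matrix(NA_integer_, 2, 4))
  expect_error(filter_samples(d3), "empty cohort")
})

test_that("ld_r2 squares Pearson correlation over shared calls", {
  expect_equal(ld_r2(c(0, 1, 2, 1), c(0, 1, 2, 1)), 1)
  expect_equal(ld_r2(c(0, 1, 2), c(2, 1, 0)), 1)
  expect_equal(ld_r2(c(0, 2, 0, 2), c(0, 0, 2, 2)), 0)
  expect_true(is.na(ld_r2(c(1, 1, 1), c(0, 1, 2))))
  expect_true(is.na(ld_r2(c(0, NA, 2), c(0, 1, NA))))
  expect_error(ld_r2(c(0, 1), c(0, 1, 2)), "length")
})

test_that("ld_prune removes duplicates, keeps independent sets intact", {
  set.seed(3)
  g <- sample(0:2, 30, replace = TRUE)
  # variants 1 and 2 identical -> exactly one survives
  d <- make_dataset(cbind(g, g, sample(0:2, 30, replace = TRUE)))
  kept <- ld_prune(d, qc_thresholds(r2_max = 0.5))
  expect_equal(sum(kept %in% 1:2), 1L)
  # all pairwise r2 below threshold -> identity
  set.seed(4)
  d2 <- make_dataset(matrix(sample(0:2, 300, replace = TRUE), nrow = 30))
  expect_equal(ld_prune(d2, qc_thresholds(r2_max = 0.99)), 1:10)
  # unsorted input errors
  d3 <- make_dataset(matrix(sample(0:2, 20, replace = TRUE), nrow = 5),
                     pos = c(300L, 100L, 200L, 400L))
  expect_error(ld_prune(d3), "sort")
})

test_that("greedy pruning matches the exhaustive maximum on the chain case", {
  # chain A ~ B, B ~ C above threshold, A-C below; MAF A=0.3 B=0.2 C=0.4
  set.seed(4)
  B <- sample(0:2, 40, replace = TRUE, prob = c(.45, .35, .2))
  A <- B; A[sample(40, 6)] <- sample(0:2, 6, replace = TRUE)
  C <- B; C[sample(40, 6)] <- sample(0:2, 6, replace = TRUE)
  r2 <- cor(cbind(A, B, C))^2
  stopifnot(r2[1, 2] > 0.5, r2[2, 3] > 0.5, r2[1, 3] <= 0.5)
  d <- make_dataset(cbind(A, B, C), pos = c(100L, 200L, 300L))
  st <- compute_variant_stats(d)
  st$maf <- c(0.3, 0.2, 0.4)
  kept <- ld_prune(d, qc_thresholds(r2_max = 0.5), stats = st)
  # greedy: pair (A,B) removes B (lower maf); pair (A,C) is under threshold
  expect_equal(kept, c(1L, 3L))
  # and {A, C} is a maximum valid subset (exhaustive over all 7 subsets)
  valid_sizes <- vapply(1:7, function(s) {
    idx <- which(bitwAnd(s, c(1L, 2L, 4L)) > 0)
    if (length(idx) < 2) return(length(idx))
    sub <- r2[idx, idx]
    if (max(sub[upper.tri(sub)]) <= 0.5) length(idx) else 0L
  }, integer(1))
  expect_equal(length(kept), max(valid_sizes))

  # randomized instances: postcondition scan + size vs exhaustive search
  set.seed(5)
  for (rep in 1:5) {
    m <- 8
    dos <- matrix(sample(0:2, 20 * m, replace = TRUE), nrow = 20)
    dd <- make_dataset(dos)
    th <- qc_thresholds(r2_max = 0.3, window = m, step = m)
    kept <- ld_prune(dd, th)
    r2 <- suppressWarnings(cor(dos)^2)
    if (length(kept) > 1) {
      sub <- r2[kept, kept]
      expect_lte(max(sub[upper.tri(sub)], na.rm = TRUE), 0.3)
    }
    # exhaustive: maximum valid subset size
    best <- 0
    for (s in 1:(2^m - 1)) {
      idx <- which(bitwAnd(s, 2^(0:(m - 1))) > 0)
      ok <- length(idx) < 2 ||
        max(r2[idx, idx][upper.tri(r2[idx, idx])], na.rm = TRUE) <= 0.3
      if (ok) best <- max(best, length(idx))
    }
    expect_lte(length(kept), best)
    expect_gte(length(kept), 1)
  }
})

test_that("pruned output satisfies the window postcondition on structured data", {
  sim <- simulate_genotypes(k_pops = 2, fst = 0.05, n_per_pop = 40,
                            n_variants = 400, seed = 21)
  th <- qc_thresholds(r2_max = 0.2, window = 50, step = 10)
  st <- compute_variant_stats(sim$data)
  keepable <- which(!is.na(st$maf) & st$maf > 0)
  d <- subset_variants(sim$data, keepable)
  kept <- ld_prune(d, th)
  v <- d$variants
  for (chr in unique(v$chrom)) {
    idx <- which(v$chrom == chr)
    s <- 1
    repeat {
      w <- idx[s:min(s + th$window - 1, length(idx))]
      act <- intersect(w, kept)
      if (length(act) > 1) {
        r2 <- suppressWarnings(cor(d$dosage[, act], use = "pairwise.complete.obs")^2)
        expect_lte(max(r2[upper.tri(r2)], na.rm = TRUE), th$r2_max)
      }
      if (s + th$window - 1 >= length(idx)) break
      s <- s + th$step
    }
  }
})
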