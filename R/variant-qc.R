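#' QC thresholds
#'
#' Bundles the variant/sample filters and LD-pruning parameters. Defaults
#' follow the PLINK-style settings used for the PC stage: MAF strictly above
#' 0.05, per-variant missingness at most 0.1, per-sample missingness at most
#' 0.2, HWE filter disabled (`hwe_min_p = 0`), and pruning with a sliding
#' window of 1000 variants advanced by 50 at a pairwise r-squared ceiling of
#' 0.05. The default excluded region is the extended HLA interval on
#' chromosome 6 (25,000,000 to 34,000,000, half-open, GRCh38).
#'
#' @param maf_min minor-allele-frequency floor; variants kept when
#'   `maf > maf_min` (strict).
#' @param geno_max maximum variant missingness fraction.
#' @param mind_max maximum sample missingness fraction (samples removed when
#'   strictly above).
#' @param hwe_min_p Hardy-Weinberg exact-test p-value floor; 0 disables.
#' @param r2_max pairwise LD ceiling for pruning.
#' @param window pruning window size, in variant count.
#' @param step window slide, in variant count.
#' @param excluded_regions data.frame with columns `chrom`, `start`, `end`
#'   (half-open intervals, `start <= pos < end`).
#' @return a list of class `QCThresholds`.
#' @export
qc_thresholds <- function(maf_min = 0.05, geno_max = 0.1, mind_max = 0.2,
                          hwe_min_p = 0, r2_max = 0.05,
                          window = 1000L, step = 50L,
                          excluded_regions = hla_region()) {
  stopifnot(maf_min >= 0, maf_min < 0.5, r2_max > 0, r2_max <= 1,
            step <= window, step >= 1)
  structure(list(maf_min = maf_min, geno_max = geno_max, mind_max = mind_max,
                 hwe_min_p = hwe_min_p, r2_max = r2_max,
                 window = as.integer(window), step = as.integer(step),
                 excluded_regions = excluded_regions),
            class = "QCThresholds")
}

#' @rdname qc_thresholds
#' @export
hla_region <- function() {
  data.frame(chrom = "6", start = 25000000L, end = 34000000L,
             stringsAsFactors = FALSE)
}

#' Per-variant summary statistics
#'
#' All statistics are computed on non-missing calls only. A variant with no
#' non-missing calls gets `call_rate` 0 and `maf` `NA` (flagged
#' `undefined`); a variant with a single segregating allele is flagged
#' `monomorphic`.
#'
#' @param data a `GenotypeDataset`.
#' @return data.frame with one row per variant: genotype counts (`n_ref_hom`,
#'   `n_het`, `n_alt_hom`), `call_rate`, `alt_freq`, `maf`, `hwe_p`,
#'   `is_palindromic`, `monomorphic`, `undefined`.
#' @export
compute_variant_stats <- function(data) {
  if (n_variants(data) == 0L) stop("dataset has no variants")
  d <- data$dosage
  n0 <- colSums(d == 0L, na.rm = TRUE)
  n1 <- colSums(d == 1L, na.rm = TRUE)
  n2 <- colSums(d == 2L, na.rm = TRUE)
  nc <- n0 + n1 + n2
  alt_freq <- ifelse(nc > 0, (2 * n2 + n1) / (2 * nc), NA_real_)
  maf <- pmin(alt_freq, 1 - alt_freq)
  hwe_p <- hwe_exact(n0, n1, n2)
  data.frame(
    n_ref_hom = n0, n_het = n1, n_alt_hom = n2,
    call_rate = nc / n_samples(data),
    alt_freq = alt_freq, maf = maf, hwe_p = hwe_p,
    is_palindromic = is_palindromic(data$variants$ref, data$variants$alt),
    monomorphic = !is.na(maf) & maf == 0,
    undefined = nc == 0,
    row.names = NULL
  )
}

#' Hardy-Weinberg exact test
#'
#' Two-sided exact test conditional on the genotype total and minor-allele
#' count: the p-value sums the probabilities of all heterozygote counts whose
#' conditional probability does not exceed that of the observed count.
#' Monomorphic input returns 1. `hwe_exact` is the vectorized form.
#'
#' @param n_ref_hom,n_het,n_alt_hom non-negative genotype counts, total >= 1.
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_ref_hom, n_het, n_alt_hom) {
  if (length(n_ref_hom) != 1L) stop("use hwe_exact() for vectors")
  if (n_ref_hom < 0 || n_het < 0 || n_alt_hom < 0) stop("negative genotype count")
  n <- n_ref_hom + n_het + n_alt_hom
  if (n < 1L) stop("at least one genotype required")
  rare <- min(2L * n_ref_hom + n_het, 2L * n_alt_hom + n_het)
  if (rare == 0L) return(1)
  hs <- seq.int(rare %% 2L, rare, by = 2L)
  # log conditional probability of h hets given n genotypes, `rare` minor alleles
  lp <- lfactorial(n) - lfactorial((rare - hs) / 2) - lfactorial(hs) -
    lfactorial(n - (rare + hs) / 2) + hs * log(2) +
    lfactorial(rare) + lfactorial(2L * n - rare) - lfactorial(2L * n)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_het, hs)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

#' @rdname hwe_exact_test
#' @export
hwe_exact <- function(n_ref_hom, n_het, n_alt_hom) {
  mapply(function(a, b, c) {
    if (a + b + c == 0L) NA_real_ else hwe_exact_test(a, b, c)
  }, n_ref_hom, n_het, n_alt_hom)
}

#' Variant-level filtering
#'
#' Applies, in order: autosomal-SNP keep (chrom in 1..22), duplicate
#' (chrom,pos,ref,alt) removal keeping the first, palindromic removal,
#' excluded-region removal, call-rate (`>= 1 - geno_max`), MAF (kept only
#' when strictly `> maf_min`; undefined/monomorphic removed here), and HWE
#' (`hwe_p >= hwe_min_p`, skipped when `hwe_min_p` is 0). A variant is
#' counted once, at the first rule that removes it, so the per-rule counts
#' plus the kept count always sum to the input count.
#'
#' @param data a `GenotypeDataset`.
#' @param stats output of [compute_variant_stats()] aligned with `data`;
#'   recomputed if `NULL`.
#' @param th a [qc_thresholds()] object.
#' @return list with `data` (filtered dataset), `removed` (named integer
#'   vector of per-rule removal counts) and `kept` (count).
#' @export
filter_variants <- function(data, stats = NULL, th = qc_thresholds()) {
  if (is.null(stats)) stats <- compute_variant_stats(data)
  stopifnot(nrow(stats) == n_variants(data))
  v <- data$variants
  n <- nrow(v)
  alive <- rep(TRUE, n)
  removed <- integer(0)

  take <- function(bad, rule) {
    bad <- bad & alive
    removed[rule] <<- sum(bad)
    alive <<- alive & !bad
  }

  take(!(v$chrom %in% as.character(1:22)), "non_autosomal")
  take(duplicated(paste(v$chrom, v$pos, v$ref, v$alt)), "duplicate")
  take(stats$is_palindromic, "palindromic")
  in_region <- rep(FALSE, n)
  reg <- th$excluded_regions
  if (!is.null(reg) && nrow(reg)) {
    for (i in seq_len(nrow(reg))) {
      in_region <- in_region |
        (v$chrom == normalize_chrom(reg$chrom[i]) &
           v$pos >= reg$start[i] & v$pos < reg$end[i])
    }
  }
  take(in_region, "excluded_region")
  take(stats$call_rate < 1 - th$geno_max, "call_rate")
  take(is.na(stats$maf) | stats$maf <= th$maf_min, "maf")
  if (th$hwe_min_p > 0) {
    take(!is.na(stats$hwe_p) & stats$hwe_p < th$hwe_min_p, "hwe")
  } else {
    removed["hwe"] <- 0L
  }

  list(data = subset_variants(data, which(alive)),
       removed = removed, kept = sum(alive))
}

#' Sample-level missingness filter
#'
#' Removes samples whose missing-call fraction is strictly greater than
#' `mind_max` ("more than 20% missing" keeps a sample at exactly 20%).
#' Variant statistics are not recomputed here; recompute them after sample
#' removal if downstream filters depend on them.
#'
#' @param data a `GenotypeDataset`.
#' @param mind_max maximum tolerated missing fraction.
#' @return list with `data` and `removed` (character vector of sample ids).
#' @export
filter_samples <- function(data, mind_max = 0.2) {
  if (n_variants(data) == 0L) stop("dataset has no variants")
  miss <- rowMeans(is.na(data$dosage))
  drop <- miss > mind_max
  if (all(drop)) stop("empty cohort: all samples exceed the missingness limit")
  list(data = subset_samples(data, which(!drop)),
       removed = data$samples[drop])
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of dosages over samples non-missing in both
#' vectors. Returns `NA` (zero-variance flag) when fewer than two shared
#' calls remain or either vector is constant on the shared support.
#'
#' @param g1,g2 equal-length dosage vectors (may contain `NA`).
#' @return r-squared in \[0, 1\], or `NA`.
#' @export
ld_r2 <- function(g1, g2) {
  if (length(g1) != length(g2)) stop("dosage vectors differ in length")
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2L) return(NA_real_)
  x <- g1[ok]; y <- g2[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Windowed LD pruning
#'
#' PLINK-style `indep-pairwise` semantics with the window measured in
#' variant count: per chromosome, a window of `th$window` variants is
#' advanced by `th$step`; within each window any still-kept pair with
#' r-squared above `th$r2_max` loses its lower-MAF member (tie: the
#' later-positioned variant is removed). The post-condition — no kept pair
#' sharing a window exceeds the threshold — is directly assertable.
#'
#' @param data a `GenotypeDataset`, variants sorted by (chrom, pos).
#' @param th a [qc_thresholds()] object.
#' @param stats optional precomputed [compute_variant_stats()].
#' @return integer vector of kept variant indices (ascending).
#' @export
ld_prune <- function(data, th = qc_thresholds(), stats = NULL) {
  v <- data$variants
  ord <- chrom_order(v$chrom, v$pos)
  if (!identical(ord, seq_len(nrow(v)))) {
    stop("variants are not sorted by (chrom, pos); sort the dataset first")
  }
  if (is.null(stats)) stats <- compute_variant_stats(data)
  maf <- stats$maf
  kept <- rep(TRUE, nrow(v))
  for (chr in unique(v$chrom)) {
    idx <- which(v$chrom == chr)
    len <- length(idx)
    s <- 1L
    repeat {
      w <- idx[s:min(s + th$window - 1L, len)]
      kept <- prune_window(data$dosage, w, kept, maf, th$r2_max)
      if (s + th$window - 1L >= len) break
      s <- s + th$step
    }
  }
  which(kept)
}

prune_window <- function(dosage, w, kept, maf, r2_max) {
  act <- w[kept[w]]
  if (length(act) < 2L) return(kept)
  r2 <- suppressWarnings(
    stats::cor(dosage[, act, drop = FALSE], use = "pairwise.complete.obs")^2
  )
  alive <- rep(TRUE, length(act))
  for (i in seq_len(length(act) - 1L)) {
    if (!alive[i]) next
    for (j in seq.int(i + 1L, length(act))) {
      if (!alive[j]) next
      r <- r2[i, j]
      if (!is.na(r) && r > r2_max) {
        # victim: lower MAF; tie -> later position
        mi <- maf[act[i]]; mj <- maf[act[j]]
        victim <- if (isTRUE(mi < mj)) i else j
        alive[victim] <- FALSE
        if (victim == i) break
      }
    }
  }
  kept[act[!alive]] <- FALSE
  kept
}
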