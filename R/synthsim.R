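#' Simulate structured genotypes under the Balding-Nichols model
#'
#' An ancestral frequency p is drawn per variant from Uniform(`p_range`);
#' each of K subpopulations draws its own frequency from
#' Beta(p (1 - F)/F, (1 - p)(1 - F)/F), so that E\[p_k\] = p and
#' Var\[p_k\] = F p (1 - p); genotypes are Binomial(2, p_k). F = 0 is the
#' degenerate no-divergence case (all populations share p exactly).
#' Variants are placed uniformly on chromosomes 1..22 and sorted by
#' position; alleles are drawn so that no variant is palindromic, keeping
#' every simulated site usable for strand-flip harmonization. Output is a
#' pure function of the parameters and seed.
#'
#' @param k_pops number of subpopulations.
#' @param fst differentiation parameter F in \[0, 1).
#' @param n_per_pop samples per subpopulation.
#' @param n_variants number of variants M.
#' @param p_range range of the ancestral allele frequency.
#' @param seed integer RNG seed.
#' @return list: `data` (a `GenotypeDataset`), `labels` (per-sample
#'   population factor, aligned with `data$samples`).
#' @export
simulate_genotypes <- function(k_pops = 3L, fst = 0.1, n_per_pop = 100L,
                               n_variants = 5000L,
                               p_range = c(0.05, 0.95), seed = 1L) {
  stopifnot(fst >= 0, fst < 1, k_pops >= 1, n_per_pop >= 1, n_variants >= 1)
  set.seed(seed)
  M <- as.integer(n_variants)
  n <- as.integer(k_pops) * as.integer(n_per_pop)
  p <- stats::runif(M, p_range[1L], p_range[2L])
  pk <- matrix(0, nrow = k_pops, ncol = M)
  if (fst == 0) {
    pk[] <- rep(p, each = k_pops)
  } else {
    a <- (1 - fst) / fst
    for (kk in seq_len(k_pops)) {
      pk[kk, ] <- stats::rbeta(M, p * a, (1 - p) * a)
    }
  }
  labels <- factor(rep(paste0("pop", seq_len(k_pops)), each = n_per_pop))
  dos <- matrix(0L, nrow = n, ncol = M)
  for (kk in seq_len(k_pops)) {
    rows <- which(as.integer(labels) == kk)
    dos[rows, ] <- stats::rbinom(length(rows) * M, 2L,
                                 rep(pk[kk, ], each = length(rows)))
  }
  chrom <- sample(as.character(1:22), M, replace = TRUE)
  pos <- integer(M)
  for (chr in unique(chrom)) {
    i <- which(chrom == chr)
    pos[i] <- sort(sample.int(2.5e8, length(i)))
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, M, replace = TRUE)
  alt <- vapply(ref, function(r) {
    sample(setdiff(bases, c(r, complement_alleles(r))), 1L)
  }, "")
  ord <- chrom_order(chrom, pos)
  variants <- data.frame(chrom = chrom[ord], pos = pos[ord], ref = ref[ord],
                         alt = alt[ord],
                         id = paste0("sv", seq_len(M)),
                         stringsAsFactors = FALSE)
  samples <- sprintf("S%04d", seq_len(n))
  data <- genotype_dataset(variants, samples, dos[, ord, drop = FALSE])
  list(data = data, labels = labels,
       ancestral_freq = p[ord], pop_freq = pk[, ord, drop = FALSE])
}

#' Derive paired array / RNA-seq ascertained genotype views
#'
#' Emulates the two genotype sources a paired-design study observes for the
#' same individuals. The array view is a random subset of variants (an
#' array-manifest ascertainment) with a small uniform missing rate. The
#' RNA-seq view sees only a "transcribed" fraction of variants and suffers
#' depth-dependent missingness (base rate optionally scaled per sample) and
#' dosage-level genotype errors: with probability `genotype_error_rate` a
#' non-missing call is replaced by one of the other two dosages, so every
#' error changes the genotype. A fraction of the RNA-seq view's variants is
#' reported on the opposite strand (ref/alt complemented in the metadata,
#' dosages untouched) to exercise flip-aware harmonization.
#'
#' @param full the truth `GenotypeDataset` from [simulate_genotypes()].
#' @param transcribed_fraction fraction of variants visible to RNA-seq.
#' @param missing_rate_base per-call missing probability in the RNA-seq view.
#' @param genotype_error_rate per-call error probability in the RNA-seq view.
#' @param array_fraction fraction of variants on the emulated array.
#' @param array_missing_rate per-call missing probability in the array view.
#' @param flip_fraction fraction of RNA-seq variants strand-complemented.
#' @param depth_effect optional per-sample multiplier on the RNA-seq missing
#'   rate (default all 1).
#' @param seed integer RNG seed.
#' @return list: `array`, `rnaseq` (both `GenotypeDataset`s), `flipped`
#'   (RNA-seq variant indices that were strand-complemented).
#' @export
derive_paired_views <- function(full, transcribed_fraction = 0.2,
                                missing_rate_base = 0.05,
                                genotype_error_rate = 0.02,
                                array_fraction = 0.6,
                                array_missing_rate = 0.01,
                                flip_fraction = 0.1,
                                depth_effect = NULL, seed = 1L) {
  stopifnot(n_variants(full) > 0)
  set.seed(seed)
  M <- n_variants(full)
  n <- n_samples(full)
  if (is.null(depth_effect)) depth_effect <- rep(1, n)
  stopifnot(length(depth_effect) == n)

  arr_idx <- sort(sample.int(M, round(array_fraction * M)))
  array_view <- subset_variants(full, arr_idx)
  miss_a <- matrix(stats::runif(n * length(arr_idx)) < array_missing_rate,
                   nrow = n)
  array_view$dosage[miss_a] <- NA_integer_

  rna_idx <- sort(sample.int(M, round(transcribed_fraction * M)))
  rna_view <- subset_variants(full, rna_idx)
  mr <- length(rna_idx)
  err <- matrix(stats::runif(n * mr) < genotype_error_rate, nrow = n)
  err <- err & !is.na(rna_view$dosage)
  if (any(err)) {
    old <- rna_view$dosage[err]
    shift <- sample(1:2, sum(err), replace = TRUE)
    rna_view$dosage[err] <- (old + shift) %% 3L
  }
  pm <- pmin(missing_rate_base * matrix(depth_effect, n, mr), 1)
  miss_r <- matrix(stats::runif(n * mr), nrow = n) < pm
  rna_view$dosage[miss_r] <- NA_integer_

  flipped <- sort(sample.int(mr, round(flip_fraction * mr)))
  rna_view$variants$ref[flipped] <-
    complement_alleles(rna_view$variants$ref[flipped])
  rna_view$variants$alt[flipped] <-
    complement_alleles(rna_view$variants$alt[flipped])
  colnames(rna_view$dosage) <- variant_key(rna_view$variants)

  list(array = array_view, rnaseq = rna_view, flipped = flipped)
}

#' Simulate confounded negative-binomial expression counts
#'
#' Gene counts follow NB(mean = s_i * 2^(b0_g + bpop_(g,k(i)) + bsex_g *
#' sex_i), dispersion phi): library-size factors s_i are log-normal, a
#' fraction of genes carries per-population mean offsets (ancestry
#' confounding) and a fraction carries a sex effect of `beta_sex` log2
#' units. Truth labels are returned per gene.
#'
#' @param labels per-sample population factor.
#' @param sex per-sample binary (0/1) vector.
#' @param n_genes number of genes.
#' @param frac_confounded fraction of genes with population-dependent means.
#' @param frac_sex_de fraction of genes with a true sex effect.
#' @param beta_pop standard deviation (log2) of per-population offsets for
#'   confounded genes.
#' @param beta_sex log2 fold change of sex-affected genes.
#' @param dispersion NB dispersion phi (rnbinom `size` = 1/phi).
#' @param lib_meanlog,lib_sdlog log-normal library-size factor parameters.
#' @param base_log2_mean range of baseline log2 mean counts.
#' @param seed integer RNG seed.
#' @return list: `counts` (genes x samples integer matrix), `truth`
#'   (data.frame: `gene`, `confounded`, `sex_de`), `lib_factor`.
#' @export
simulate_counts <- function(labels, sex, n_genes = 2000L,
                            frac_confounded = 0.1, frac_sex_de = 0.05,
                            beta_pop = 1.0, beta_sex = 1.0,
                            dispersion = 0.3,
                            lib_meanlog = 0, lib_sdlog = 0.25,
                            base_log2_mean = c(1, 9), seed = 1L) {
  stopifnot(length(labels) == length(sex))
  set.seed(seed)
  labels <- as.factor(labels)
  n <- length(labels)
  K <- nlevels(labels)
  G <- as.integer(n_genes)
  confounded <- seq_len(G) <= round(frac_confounded * G)
  sex_de <- rep(FALSE, G)
  sex_de[sample.int(G, round(frac_sex_de * G))] <- TRUE

  b0 <- stats::runif(G, base_log2_mean[1L], base_log2_mean[2L])
  bpop <- matrix(0, nrow = G, ncol = K)
  bpop[confounded, ] <- stats::rnorm(sum(confounded) * K, 0, beta_pop)
  bsex <- ifelse(sex_de, beta_sex * sample(c(-1, 1), G, replace = TRUE), 0)
  s <- stats::rlnorm(n, lib_meanlog, lib_sdlog)

  log2mu <- matrix(b0, G, n) + bpop[, as.integer(labels), drop = FALSE] +
    outer(bsex, sex)
  mu <- sweep(2^log2mu, 2L, s, "*")
  counts <- matrix(stats::rnbinom(G * n, size = 1 / dispersion, mu = mu),
                   nrow = G)
  rownames(counts) <- sprintf("gene%05d", seq_len(G))
  colnames(counts) <- names(labels) %||% sprintf("S%04d", seq_len(n))
  list(counts = counts,
       truth = data.frame(gene = rownames(counts), confounded = confounded,
                          sex_de = sex_de, stringsAsFactors = FALSE),
       lib_factor = s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sex assignment with optional ancestry imbalance
#'
#' Draws a binary sex indicator per sample; with `imbalance = 0` the male
#' probability is 0.5 in every population (the balanced null); positive
#' imbalance spreads the per-population male probabilities linearly across
#' `0.5 +/- imbalance/2`, confounding sex with ancestry.
#'
#' @param labels per-sample population factor.
#' @param imbalance in \[0, 1\].
#' @param seed integer RNG seed.
#' @return integer 0/1 vector.
#' @export
simulate_sex <- function(labels, imbalance = 0, seed = 1L) {
  set.seed(seed)
  labels <- as.factor(labels)
  K <- nlevels(labels)
  probs <- if (K == 1L) 0.5 else
    0.5 + imbalance * (seq_len(K) - (K + 1) / 2) / (K - 1)
  as.integer(stats::runif(length(labels)) < probs[as.integer(labels)])
}
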