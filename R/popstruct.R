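#' Standardize genotypes for PCA / GRM
#'
#' Binomial standardization: for alt-allele frequency p_j (estimated from
#' the non-missing calls of this dataset), a non-missing dosage g becomes
#' z = (g - 2 p_j) / sqrt(2 p_j (1 - p_j)); missing calls become exactly 0
#' (mean imputation). Monomorphic variants (p_j of 0 or 1) are an error —
#' filter on MAF first. An all-heterozygote column (p = 0.5) standardizes to
#' all zeros; it is kept and flagged zero-variance.
#'
#' @param data a `GenotypeDataset`.
#' @return list of class `StandardizedMatrix`: `Z` (samples x variants),
#'   `freqs` (alt-allele frequencies used), `zero_variance` (logical per
#'   variant), `n_samples`, `n_variants`, `samples`.
#' @export
standardize <- function(data) {
  d <- data$dosage
  p <- colMeans(d, na.rm = TRUE) / 2
  bad <- which(is.na(p) | p <= 0 | p >= 1)
  if (length(bad)) {
    stop("monomorphic or all-missing variant(s): ",
         paste(utils::head(colnames(d)[bad], 5L), collapse = ", "),
         if (length(bad) > 5L) " ..." else "")
  }
  Z <- sweep(d, 2L, 2 * p, "-")
  Z <- sweep(Z, 2L, sqrt(2 * p * (1 - p)), "/")
  Z[is.na(Z)] <- 0
  zero_var <- apply(Z, 2L, function(col) all(col == 0))
  structure(list(Z = Z, freqs = p, zero_variance = zero_var,
                 n_samples = nrow(Z), n_variants = ncol(Z),
                 samples = data$samples),
            class = "StandardizedMatrix")
}

#' Genetic principal components of standardized genotypes
#'
#' Eigendecomposition of (1/m) Z Z' with m the variant count. Scores are
#' principal-component scores — eigenvectors scaled by sqrt(n * eigenvalue)
#' — and loadings are the corresponding right singular directions of Z.
#' The sign of each component is fixed deterministically: the loading of
#' largest absolute value is made positive (falling back to the score of
#' largest absolute value for null components), so repeated runs on the
#' same input are bit-stable.
#'
#' @param Z a `StandardizedMatrix` (or bare numeric matrix).
#' @param k number of components, `k <= min(n_samples - 1, n_variants)`.
#' @return list of class `PCResult`: `k`, `scores` (samples x k),
#'   `loadings` (variants x k), `eigenvalues` (non-increasing, length k),
#'   `freqs`, `samples`.
#' @export
compute_pcs <- function(Z, k = 10L) {
  freqs <- NULL; samples <- NULL
  if (inherits(Z, "StandardizedMatrix")) {
    freqs <- Z$freqs; samples <- Z$samples; Z <- Z$Z
  }
  n <- nrow(Z); m <- ncol(Z)
  if (is.null(samples)) samples <- rownames(Z)
  if (k > min(n - 1L, m)) {
    stop("k must be at most min(n_samples - 1, n_variants) = ",
         min(n - 1L, m))
  }
  C <- tcrossprod(Z) / m
  e <- eigen(C, symmetric = TRUE)
  lam <- pmax(e$values[seq_len(k)], 0)
  U <- e$vectors[, seq_len(k), drop = FALSE]
  d <- sqrt(m * lam)                        # singular values of Z
  V <- matrix(0, nrow = m, ncol = k)
  tol <- max(d[1L], 1) * 1e-12
  for (i in seq_len(k)) {
    if (d[i] > tol) V[, i] <- crossprod(Z, U[, i, drop = FALSE]) / d[i]
  }
  for (i in seq_len(k)) {
    ref <- if (any(V[, i] != 0)) V[, i] else U[, i]
    j <- which.max(abs(ref))
    if (ref[j] < 0) {
      V[, i] <- -V[, i]
      U[, i] <- -U[, i]
    }
  }
  scores <- sweep(U, 2L, sqrt(n * lam), "*")
  rownames(scores) <- samples
  colnames(scores) <- paste0("PC", seq_len(k))
  colnames(V) <- paste0("PC", seq_len(k))
  structure(list(k = as.integer(k), scores = scores, loadings = V,
                 eigenvalues = lam, freqs = freqs, samples = samples),
            class = "PCResult")
}

#' @export
print.PCResult <- function(x, ...) {
  cat(sprintf("PCResult: %d samples, %d components\n",
              nrow(x$scores), x$k))
  cat("  eigenvalues:", paste(signif(utils::head(x$eigenvalues, 5L), 4L),
                              collapse = ", "),
      if (x$k > 5L) "..." else "", "\n")
  invisible(x)
}

#' Joint PCA of two cohorts
#'
#' Harmonizes the two datasets (strand-flip aware matching on (chrom, pos)),
#' stacks the samples over the shared variants, re-standardizes on the
#' merged cohort (frequencies re-estimated jointly, not projected), and
#' computes principal components. Sample ids are made unique across cohorts
#' where they collide.
#'
#' @param a,b QC'd `GenotypeDataset`s.
#' @param k number of components.
#' @param labels length-2 character vector of cohort labels.
#' @return list: `pc` (a `PCResult`), `cohort` (per-sample label, in score
#'   row order), `n_overlap` (shared usable variant count).
#' @export
joint_pca <- function(a, b, k = 10L, labels = c("A", "B")) {
  matches <- match_variants(a, b)
  usable <- matches[matches$action %in% matched_actions, , drop = FALSE]
  if (nrow(usable) == 0L) stop("no overlapping variants between cohorts")
  if (nrow(usable) < 100L) {
    warning("only ", nrow(usable), " overlapping variants between cohorts")
  }
  a_sub <- subset_variants(a, usable$index_a)
  b_al <- align_genotypes(b, matches)
  ids <- make.unique(c(paste0(a_sub$samples), paste0(b_al$samples)),
                     sep = "_dup")
  merged <- genotype_dataset(
    a_sub$variants, ids,
    rbind(a_sub$dosage, b_al$dosage)
  )
  pc <- compute_pcs(standardize(merged), k)
  cohort <- rep(labels, c(n_samples(a), n_samples(b)))
  list(pc = pc, cohort = cohort, n_overlap = nrow(usable))
}

#' Genomic relationship matrix
#'
#' GRM = Z Z' / m on the standardized genotype matrix: the covariance
#' structure of the polygenic random effect in the mixed model.
#'
#' @param Z a `StandardizedMatrix` (or bare matrix).
#' @return list of class `GRM`: `matrix` (samples x samples, symmetric),
#'   `n_variants_used`, `samples`.
#' @export
compute_grm <- function(Z) {
  samples <- NULL
  if (inherits(Z, "StandardizedMatrix")) {
    samples <- Z$samples; Z <- Z$Z
  }
  m <- ncol(Z)
  stopifnot(m >= 1L)
  G <- tcrossprod(Z) / m
  G <- (G + t(G)) / 2
  if (!is.null(samples)) dimnames(G) <- list(samples, samples)
  structure(list(matrix = G, n_variants_used = m, samples = samples),
            class = "GRM")
}

#' @export
print.GRM <- function(x, ...) {
  cat(sprintf("GRM: %d x %d from %d variants; mean diagonal %.4f\n",
              nrow(x$matrix), ncol(x$matrix), x$n_variants_used,
              mean(diag(x$matrix))))
  invisible(x)
}
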