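#' Low-expression filtering by CPM
#'
#' Keeps genes whose counts-per-million exceed `cpm_min` (strictly) in at
#' least `ceiling(sample_frac * n_samples)` samples; optionally restricts to
#' autosomal genes when a chromosome annotation is supplied.
#'
#' @param counts genes x samples non-negative integer matrix with gene ids
#'   as rownames.
#' @param cpm_min CPM threshold (default 0.05, strict).
#' @param sample_frac minimum fraction of samples above threshold
#'   (default 0.2).
#' @param gene_chrom optional per-gene chromosome labels (same order as
#'   rows); when given with `autosomal_only = TRUE`, only genes on
#'   chromosomes 1..22 are kept.
#' @param autosomal_only apply the autosomal filter.
#' @return the filtered count matrix.
#' @export
cpm_filter <- function(counts, cpm_min = 0.05, sample_frac = 0.2,
                       gene_chrom = NULL, autosomal_only = !is.null(gene_chrom)) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  if (any(lib <= 0)) {
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[lib <= 0], collapse = ", "))
  }
  keep <- rep(TRUE, nrow(counts))
  if (autosomal_only) {
    if (is.null(gene_chrom)) stop("autosomal_only requires gene_chrom")
    keep <- normalize_chrom(gene_chrom) %in% as.character(1:22)
  }
  cpm <- sweep(counts, 2L, lib, "/") * 1e6
  need <- ceiling(sample_frac * ncol(counts))
  keep <- keep & (rowSums(cpm > cpm_min) >= need)
  counts[keep, , drop = FALSE]
}

#' log2 counts-per-million
#'
#' Fixed offset convention: log2((count + 0.5) / (libsize + 1) * 1e6).
#'
#' @param counts genes x samples count matrix.
#' @param lib_size per-sample library sizes; defaults to the column sums.
#'   Passing them explicitly (e.g. totals computed before gene filtering)
#'   makes the per-gene statistics independent of which other genes are in
#'   the matrix.
#' @return genes x samples real matrix.
#' @export
log2_cpm <- function(counts, lib_size = NULL) {
  counts <- as.matrix(counts)
  lib <- if (is.null(lib_size)) colSums(counts) else lib_size
  stopifnot(length(lib) == ncol(counts))
  log2(sweep(counts + 0.5, 2L, lib + 1, "/") * 1e6)
}

build_design <- function(n, trait, covariates = NULL, pcs = NULL) {
  trait <- as.numeric(trait)
  stopifnot(length(trait) == n)
  X <- cbind(`(Intercept)` = 1, trait = trait)
  if (!is.null(covariates)) {
    cov_df <- as.data.frame(covariates)
    if (anyNA(cov_df)) stop("missing values in covariates")
    mm <- stats::model.matrix(~ ., data = cov_df)[, -1L, drop = FALSE]
    X <- cbind(X, mm)
  }
  if (!is.null(pcs)) {
    pcs <- as.matrix(pcs)
    if (is.null(colnames(pcs))) colnames(pcs) <- paste0("PC", seq_len(ncol(pcs)))
    X <- cbind(X, pcs)
  }
  X
}

#' Per-gene linear-model differential expression
#'
#' Ordinary least squares of log2-CPM on \[intercept, trait, covariates,
#' optional genetic PCs\], per gene. The reported effect is the trait
#' coefficient ("logFC" in log2-CPM units per trait unit); the t statistic
#' uses the residual degrees of freedom; the chi-square statistic is the
#' 1-df quantile equivalent of the two-sided p-value (the z-squared
#' convention, which makes the inflation metric m engine-agnostic); q-values
#' are Benjamini-Hochberg.
#'
#' @param counts genes x samples count matrix (gene ids as rownames).
#' @param trait per-sample numeric or binary trait of interest.
#' @param covariates optional per-sample data.frame of nuisance covariates
#'   (factors expanded via model.matrix).
#' @param pcs optional samples x k matrix of genetic PC scores.
#' @param lib_size optional per-sample library sizes (see [log2_cpm()]).
#' @return data.frame of class `DGEResult`, one row per gene: `gene`,
#'   `logFC`, `se`, `t`, `p_value`, `chisq`, `q_value`, `underflow`.
#' @export
dge_lm <- function(counts, trait, covariates = NULL, pcs = NULL,
                   lib_size = NULL) {
  counts <- as.matrix(counts)
  n <- ncol(counts)
  X <- build_design(n, trait, covariates, pcs)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  df <- n - ncol(X)
  if (df < 2L) {
    stop("too many covariates/PCs: residual degrees of freedom ", df, " < 2")
  }
  Y <- t(log2_cpm(counts, lib_size))             # samples x genes
  B <- qr.coef(qrX, Y)
  res <- Y - X %*% B
  sigma2 <- colSums(res^2) / df
  inv_pivoted <- chol2inv(qr.R(qrX))
  XtXinv <- matrix(0, ncol(X), ncol(X))
  XtXinv[qrX$pivot, qrX$pivot] <- inv_pivoted
  v_trait <- XtXinv[2L, 2L]
  beta <- B["trait", ]
  se <- sqrt(sigma2 * v_trait)
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df = df)
  underflow <- p < 1e-300
  p_floor <- pmax(p, 1e-300)
  chisq <- stats::qchisq(p_floor, df = 1, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(gene = rownames(counts), logFC = beta, se = se, t = tstat,
                    p_value = p, chisq = chisq, q_value = q,
                    underflow = underflow,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("DGEResult", "data.frame")
  out
}

#' Systematic inflation metric m
#'
#' Ratio of the median empirical chi-square statistic of the adjusted
#' analysis (with genetic PCs) to that of the unadjusted analysis, computed
#' on the identical feature set. Values below 1 indicate that the PCs
#' absorbed stratification that was inflating the unadjusted statistics.
#'
#' @param with_pcs,without_pcs `DGEResult`s (or any data.frames with `gene`
#'   and `chisq` columns) over identical gene sets in identical order.
#' @return list of class `InflationReport`: `median_chisq_with_pcs`,
#'   `median_chisq_without_pcs`, `m`, `n_features`.
#' @export
inflation_m <- function(with_pcs, without_pcs) {
  id_w <- if ("gene" %in% names(with_pcs)) with_pcs$gene else with_pcs$id
  id_o <- if ("gene" %in% names(without_pcs)) without_pcs$gene else without_pcs$id
  if (!identical(id_w, id_o)) {
    stop("feature sets of the two analyses differ (ids or order)")
  }
  mw <- stats::median(with_pcs$chisq)
  mo <- stats::median(without_pcs$chisq)
  structure(list(median_chisq_with_pcs = mw,
                 median_chisq_without_pcs = mo,
                 m = mw / mo, n_features = length(id_w)),
            class = "InflationReport")
}

#' @export
print.InflationReport <- function(x, ...) {
  cat(sprintf("InflationReport: m = %.4f (median chisq %.4f with PCs / %.4f without, %d features)\n",
              x$m, x$median_chisq_with_pcs, x$median_chisq_without_pcs,
              x$n_features))
  invisible(x)
}

#' Chi-square quantile-quantile plot of two analyses
#'
#' Plots observed -log10 p of the adjusted and unadjusted analyses against
#' the uniform expectation. Requires ggplot2.
#'
#' @param without_pcs,with_pcs `DGEResult`s (or vectors of p-values).
#' @return a ggplot object.
#' @export
qq_plot <- function(without_pcs, with_pcs = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("qq_plot requires ggplot2")
  }
  grab <- function(x) if (is.data.frame(x)) x$p_value else as.numeric(x)
  frames <- list(`without PCs` = grab(without_pcs))
  if (!is.null(with_pcs)) frames$`with PCs` <- grab(with_pcs)
  df <- do.call(rbind, lapply(names(frames), function(nm) {
    p <- sort(frames[[nm]])
    data.frame(expected = -log10(stats::ppoints(length(p))),
               observed = -log10(pmax(p, 1e-300)), analysis = nm)
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$expected, .data$observed,
                                   colour = .data$analysis)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p)))
}
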