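#' Spearman correlation matrix between two PC score sets
#'
#' Rank-transform then Pearson (ties mid-ranked); p-values from the t
#' approximation with n - 2 degrees of freedom. Cells involving a constant
#' column are `NA` (undefined) in both matrices.
#'
#' @param x,y numeric matrices, samples x components, same sample order,
#'   n >= 3.
#' @return list of class `PCCorrelationMatrix`: `rho`, `p`.
#' @export
spearman_matrix <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("score matrices must share the sample set")
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 samples")
  rho <- suppressWarnings(stats::cor(x, y, method = "spearman"))
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1] <- 0
  p[is.na(rho)] <- NA_real_
  structure(list(rho = rho, p = p), class = "PCCorrelationMatrix")
}

#' Canonical correlation analysis of two score blocks
#'
#' Columns are centered internally; each block is reduced to an orthonormal
#' basis by pivoted QR (rank-deficient blocks reduce the number of canonical
#' dimensions, with a warning) and the canonical correlations are the
#' singular values of the cross-product of the two bases. This makes the
#' result invariant, up to numerical tolerance, to any invertible linear
#' re-mixing of either block's columns. Canonical variates are returned as
#' the orthonormal-basis combinations, so the sample correlation of the
#' i-th pair equals R_ci.
#'
#' @param x,y numeric matrices, samples x p and samples x q, same sample
#'   order. A warning is given when n <= p + q.
#' @return list of class `CCAResult`: `cor` (canonical correlations,
#'   non-increasing, in \[0,1\]), `x_variates`, `y_variates` (samples x s),
#'   `n`, `p`, `q`, `s`.
#' @export
canonical_correlation <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("blocks must share the sample set")
  n <- nrow(x); p <- ncol(x); q <- ncol(y)
  if (n <= p + q) {
    warning("n <= p + q: canonical correlations will be upward biased")
  }
  xc <- scale(x, center = TRUE, scale = FALSE)
  yc <- scale(y, center = TRUE, scale = FALSE)
  qx <- qr(xc)
  qy <- qr(yc)
  rx <- qx$rank; ry <- qy$rank
  if (rx < p || ry < q) {
    warning("rank-deficient block; using ", rx, " x ", ry,
            " effective dimensions")
  }
  if (rx == 0L || ry == 0L) stop("a block has no variation")
  Qx <- qr.Q(qx)[, seq_len(rx), drop = FALSE]
  Qy <- qr.Q(qy)[, seq_len(ry), drop = FALSE]
  sv <- svd(crossprod(Qx, Qy))
  s <- min(rx, ry)
  rc <- pmin(pmax(sv$d[seq_len(s)], 0), 1)
  xv <- Qx %*% sv$u[, seq_len(s), drop = FALSE]
  yv <- Qy %*% sv$v[, seq_len(s), drop = FALSE]
  colnames(xv) <- colnames(yv) <- paste0("CV", seq_len(s))
  structure(list(cor = rc, x_variates = xv, y_variates = yv,
                 n = n, p = p, q = q, s = s),
            class = "CCAResult")
}

#' Wilks' Lambda sequential tests for canonical dimensions
#'
#' For k = 1..s, Lambda_k = prod_(i>=k) (1 - R_ci^2); Bartlett's chi-square
#' approximation uses statistic -(n - 1 - (p + q + 1)/2) log Lambda_k with
#' (p - k + 1)(q - k + 1) degrees of freedom. A Lambda of exactly 0
#' (perfect canonical correlation) is reported with p-value 0 and flagged
#' `underflow`.
#'
#' @param result a `CCAResult`, or a bare vector of canonical correlations.
#' @param n,p,q sample size and block widths (taken from `result` when it is
#'   a `CCAResult`).
#' @return data.frame: `k`, `r_c`, `lambda`, `chisq`, `df`, `p_value`,
#'   `underflow`.
#' @export
wilks_sequential_test <- function(result, n = NULL, p = NULL, q = NULL) {
  if (inherits(result, "CCAResult")) {
    rc <- result$cor
    if (is.null(n)) n <- result$n
    if (is.null(p)) p <- result$p
    if (is.null(q)) q <- result$q
  } else {
    rc <- result
  }
  stopifnot(!is.null(n), !is.null(p), !is.null(q))
  if (n <= p + q + 1) warning("n <= p + q + 1: Bartlett approximation is poor")
  s <- length(rc)
  lambda <- rev(cumprod(rev(1 - rc^2)))
  scale_f <- n - 1 - (p + q + 1) / 2
  chisq <- ifelse(lambda > 0, -scale_f * log(lambda), Inf)
  df <- (p - seq_len(s) + 1) * (q - seq_len(s) + 1)
  p_value <- stats::pchisq(chisq, df = df, lower.tail = FALSE)
  underflow <- lambda <= 0 | p_value < .Machine$double.xmin
  p_value[lambda <= 0] <- 0
  data.frame(k = seq_len(s), r_c = rc, lambda = lambda, chisq = chisq,
             df = df, p_value = p_value, underflow = underflow)
}

#' Shared variance (redundancy index) between two PC sets
#'
#' For canonical variate i, the redundancy of block Y given X's structure is
#' Rd_i = R_ci^2 times the mean, over Y's (standardized) columns, of the
#' squared correlation between the column and Y's i-th canonical variate —
#' the proportion of Y's total variance explained through dimension i. The
#' cumulative sum over variates is the "proportion of shared variance"
#' summary. The same quantity in the other direction (X given Y) is also
#' reported.
#'
#' @param result a `CCAResult` from [canonical_correlation()].
#' @param x,y the original blocks (standardized internally).
#' @return data.frame: `k`, `rc2`, `rd_y` (redundancy of Y given X's
#'   variates), `cum_rd_y`, `rd_x`, `cum_rd_x`.
#' @export
shared_variance <- function(result, x, y) {
  stopifnot(inherits(result, "CCAResult"))
  ys <- scale(as.matrix(y))
  xs <- scale(as.matrix(x))
  rc2 <- result$cor^2
  # intra-block variate loadings
  ly <- suppressWarnings(stats::cor(ys, result$y_variates))
  lx <- suppressWarnings(stats::cor(xs, result$x_variates))
  rd_y <- rc2 * colMeans(ly^2, na.rm = TRUE)
  rd_x <- rc2 * colMeans(lx^2, na.rm = TRUE)
  data.frame(k = seq_along(rc2), rc2 = rc2,
             rd_y = rd_y, cum_rd_y = cumsum(rd_y),
             rd_x = rd_x, cum_rd_x = cumsum(rd_x))
}

#' Full two-block comparison
#'
#' Convenience wrapper: Spearman matrix, CCA, Wilks sequential tests and
#' shared variance in one call.
#'
#' @param x,y PC score matrices over the same samples (x: the RNA-seq-derived
#'   set, y: the reference/array set whose structure is to be explained).
#' @return list: `spearman`, `cca`, `wilks`, `shared` (one row per variate).
#' @export
compare_pc_sets <- function(x, y) {
  sp <- spearman_matrix(x, y)
  cca <- canonical_correlation(x, y)
  wk <- wilks_sequential_test(cca)
  sh <- shared_variance(cca, x, y)
  list(spearman = sp, cca = cca, wilks = wk, shared = sh)
}
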