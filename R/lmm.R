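#' REML linear mixed model with a GRM random effect
#'
#' Fits y = X beta + g + e with g ~ N(0, sigma_g^2 * GRM) and
#' e ~ N(0, sigma_e^2 * I). The GRM is eigendecomposed once; the restricted
#' likelihood is profiled over the variance ratio gamma = sigma_g^2 /
#' sigma_e^2 by a coarse grid on log10(gamma) refined by 1-D optimization
#' (tolerance 1e-6 on the log-likelihood argument), with the gamma = 0
#' boundary always evaluated. Fixed effects and Wald statistics come from
#' GLS at the optimum.
#'
#' When the GRM is the identity the two components are not separately
#' identifiable; the fit is flagged and the contract is that the total
#' variance matches the OLS residual variance and Wald statistics match OLS.
#'
#' @param y numeric phenotype vector.
#' @param X fixed-effect design matrix (include the intercept), full rank.
#' @param grm a `GRM` from [compute_grm()] or a bare symmetric matrix
#'   aligned with `y`.
#' @param gamma_grid log10-spaced grid of variance ratios to bracket the
#'   optimum.
#' @return list of class `LMMFit`: `sigma_g2`, `sigma_e2`, `ratio`
#'   (sigma_g^2 / (sigma_g^2 + sigma_e^2)), `gamma`, `loglik` (restricted),
#'   `beta`, `se`, `wald` (per-predictor chi-square), `converged`,
#'   `eigen` (reusable decomposition).
#' @export
reml_lmm <- function(y, X, grm, gamma_grid = 10^seq(-4, 4, by = 0.25)) {
  X <- as.matrix(X)
  G <- if (inherits(grm, "GRM")) grm$matrix else as.matrix(grm)
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(G) == n, ncol(G) == n)
  p <- ncol(X)
  if (qr(X)$rank < p) stop("fixed-effect design is rank deficient")
  ed <- if (is.list(grm) && !is.null(grm$eigen_cache)) grm$eigen_cache else
    eigen(G, symmetric = TRUE)
  lam <- ed$values
  if (min(lam) < -1e-8 * sum(pmax(lam, 0)) / n) {
    stop("GRM is not positive semidefinite beyond tolerance")
  }
  lam <- pmax(lam, 0)
  U <- ed$vectors
  ys <- drop(crossprod(U, y))
  Xs <- crossprod(U, X)

  nll <- function(log10_gamma) -reml_ll(10^log10_gamma, ys, Xs, lam, p)

  vals <- vapply(log10(gamma_grid), nll, numeric(1))
  best <- which.min(vals)
  lo <- log10(gamma_grid[max(1L, best - 1L)])
  hi <- log10(gamma_grid[min(length(gamma_grid), best + 1L)])
  opt <- stats::optimize(nll, lower = lo, upper = hi, tol = 1e-6)
  ll0 <- reml_ll(0, ys, Xs, lam, p)               # boundary sigma_g^2 = 0
  if (ll0 >= -opt$objective) {
    gamma <- 0; ll <- ll0
  } else {
    gamma <- 10^opt$minimum; ll <- -opt$objective
  }
  converged <- is.finite(ll)

  w <- 1 / (gamma * lam + 1)
  sw <- sqrt(w)
  Xw <- Xs * sw
  yw <- ys * sw
  fit <- stats::lm.fit(Xw, yw)
  rss <- sum(fit$residuals^2)
  sigma_e2 <- rss / (n - p)
  sigma_g2 <- gamma * sigma_e2
  XtX <- crossprod(Xw)
  cov_beta <- sigma_e2 * solve(XtX)
  beta <- fit$coefficients
  se <- sqrt(diag(cov_beta))
  structure(list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
                 ratio = sigma_g2 / (sigma_g2 + sigma_e2),
                 gamma = gamma, loglik = ll, beta = beta, se = se,
                 wald = (beta / se)^2, converged = converged,
                 eigen = ed),
            class = "LMMFit")
}

# restricted log-likelihood, constants dropped, profiled over sigma_e^2
reml_ll <- function(gamma, ys, Xs, lam, p) {
  n <- length(ys)
  w <- 1 / (gamma * lam + 1)
  sw <- sqrt(w)
  Xw <- Xs * sw
  yw <- ys * sw
  fit <- stats::lm.fit(Xw, yw)
  rss <- sum(fit$residuals^2)
  if (rss <= 0) return(-Inf)
  sigma_e2 <- rss / (n - p)
  ld_v <- -sum(log(w))                       # log det of (gamma*K + I)
  ld_x <- determinant(crossprod(Xw), logarithm = TRUE)$modulus
  -0.5 * ((n - p) * log(sigma_e2) + ld_v + as.numeric(ld_x) + (n - p))
}

#' Per-variant mixed-model association scan
#'
#' Variance components are estimated once under the null model (covariates
#' and optional PCs, no variant), then every variant is tested by GLS with
#' the components held fixed: missing dosages are mean-imputed, the variant
#' is residualized against the null design in the whitened space, and a
#' 1-df Wald chi-square is reported. Monomorphic variants get `NA`.
#'
#' @param y phenotype vector.
#' @param variants a `GenotypeDataset` over the same samples (same order).
#' @param grm a `GRM` (use `diag(n)` for the no-relatedness OLS limit).
#' @param pcs optional samples x k matrix of PC scores (fixed-effect
#'   covariates).
#' @param covariates optional per-sample data.frame.
#' @return list: `stats` (data.frame with `id`, `beta`, `se`, `chisq`,
#'   `p_value` per variant) and `fit` (the null `LMMFit`).
#' @export
lmm_scan <- function(y, variants, grm, pcs = NULL, covariates = NULL) {
  n <- length(y)
  stopifnot(n_samples(variants) == n)
  X0 <- build_design(n, rep(0, n), covariates, pcs)
  X0 <- X0[, colnames(X0) != "trait", drop = FALSE]
  fit <- reml_lmm(y, X0, grm)
  lam <- pmax(fit$eigen$values, 0)
  U <- fit$eigen$vectors
  sw <- sqrt(1 / (fit$gamma * lam + 1))
  Xw <- crossprod(U, X0) * sw
  yw <- drop(crossprod(U, y)) * sw
  qr0 <- qr(Xw)
  yr <- qr.resid(qr0, yw)
  sigma_e2 <- fit$sigma_e2

  D <- variants$dosage
  mu <- colMeans(D, na.rm = TRUE)
  ids <- variant_key(variants$variants)
  res <- data.frame(id = ids, beta = NA_real_, se = NA_real_,
                    chisq = NA_real_, p_value = NA_real_,
                    stringsAsFactors = FALSE)
  Gw <- crossprod(U, imputed_dosage(D, mu)) * sw
  Gr <- qr.resid(qr0, Gw)
  ss <- colSums(Gr^2)
  ok <- ss > 1e-10
  beta <- colSums(Gr * yr) / ss
  se <- sqrt(sigma_e2 / ss)
  chisq <- (beta / se)^2
  res$beta[ok] <- beta[ok]
  res$se[ok] <- se[ok]
  res$chisq[ok] <- chisq[ok]
  res$p_value[ok] <- stats::pchisq(chisq[ok], df = 1, lower.tail = FALSE)
  list(stats = res, fit = fit)
}

imputed_dosage <- function(D, mu) {
  Z <- matrix(as.numeric(D), nrow(D), ncol(D))
  idx <- which(is.na(Z), arr.ind = TRUE)
  if (nrow(idx)) Z[idx] <- mu[idx[, 2L]]
  Z
}

#' Inflation between two association scans
#'
#' The metric m of [inflation_m()] applied to the per-variant chi-squares of
#' two [lmm_scan()] runs (typically with and without PCs) over the same
#' variants; `NA` statistics are dropped pairwise.
#'
#' @param scan_with,scan_without outputs of [lmm_scan()].
#' @return an `InflationReport`.
#' @export
scan_inflation <- function(scan_with, scan_without) {
  sw <- scan_with$stats
  so <- scan_without$stats
  if (!identical(sw$id, so$id)) stop("scans cover different variant sets")
  ok <- !is.na(sw$chisq) & !is.na(so$chisq)
  inflation_m(sw[ok, c("id", "chisq")], so[ok, c("id", "chisq")])
}
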