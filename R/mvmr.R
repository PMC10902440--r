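#' Multivariable IVW regression
#'
#' Conditions each exposure's causal effect on the co-exposures: weighted
#' least squares of outcome betas on the matrix of exposure betas with no
#' intercept and weights `1/se_out^2`, over the instrument union (every
#' exposure's beta must be observed at every SNP). Per-exposure standard
#' errors come from the WLS covariance with the multiplicative
#' over-dispersion floor used by univariable random-effects IVW.
#'
#' @param beta_exp Numeric matrix or data frame of exposure betas
#'   (SNPs x exposures); column names label the exposures.
#' @param beta_out,se_out Outcome betas and standard errors.
#' @param snp Optional SNP ids (used in PRESSO reporting).
#' @return A tibble with one row per exposure: `exposure`, `n_snp`, `b`,
#'   `se`, `pval`, `or`, `or_lo`, `or_hi`.
#' @export
mvmr_ivw <- function(beta_exp, beta_out, se_out, snp = NULL) {
  X <- as.matrix(beta_exp)
  if (is.null(colnames(X))) colnames(X) <- paste0("exposure", seq_len(ncol(X)))
  k <- nrow(X)
  p <- ncol(X)
  stopifnot(length(beta_out) == k, length(se_out) == k, all(se_out > 0))
  if (k <= p) abort("mvmr_ivw requires more SNPs than exposures")
  if (anyNA(X)) abort("mvmr_ivw: missing exposure betas are disallowed")
  if (qr(X)$rank < p) abort("collinear exposures")
  w <- 1 / se_out^2
  Xw <- X * sqrt(w)
  yw <- beta_out * sqrt(w)
  fit <- qr.solve(crossprod(Xw), crossprod(Xw, yw))
  resid <- yw - Xw %*% fit
  sigma2 <- sum(resid^2) / (k - p)
  disp <- max(1, sigma2)
  V <- disp * solve(crossprod(Xw))
  b <- unname(drop(fit))
  se <- unname(sqrt(diag(V)))
  ci <- qnorm(0.975)
  tibble(exposure = colnames(X), n_snp = k, b = b, se = se,
         pval = 2 * pnorm(-abs(b / se)),
         or = exp(b), or_lo = exp(b - ci * se), or_hi = exp(b + ci * se))
}

#' MR-PRESSO global test for a multivariable fit
#'
#' Applies the same leave-one-out residual-simulation machinery as
#' [mr_presso()] to the multivariable IVW regression: the observed
#' statistic sums weighted squared residuals of each SNP around the fit
#' that excludes it, the null is built by redrawing outcome betas around
#' the leave-one-out fitted values, and outliers are flagged by
#' Bonferroni-corrected per-SNP p-values.
#'
#' @inheritParams mvmr_ivw
#' @param n_sim Number of null simulations.
#' @param outlier_alpha Outlier significance level.
#' @param seed Optional seed.
#' @return An `mr_presso` object; `corrected` holds the outlier-removed
#'   [mvmr_ivw()] table when outliers are flagged.
#' @export
mvmr_presso <- function(beta_exp, beta_out, se_out, snp = NULL,
                        n_sim = 1000, outlier_alpha = 0.05, seed = NULL) {
  X <- as.matrix(beta_exp)
  if (is.null(colnames(X))) colnames(X) <- paste0("exposure", seq_len(ncol(X)))
  k <- nrow(X)
  p <- ncol(X)
  if (k <= p + 2) abort("mvmr_presso requires more than exposures + 2 SNPs")
  snp <- snp %||% sprintf("snp%03d", seq_len(k))
  w <- 1 / se_out^2

  XtWX <- crossprod(X * sqrt(w))
  XtWy <- crossprod(X, w * beta_out)
  Ainv <- vector("list", k)
  mu_loo <- numeric(k)
  for (j in seq_len(k)) {
    xj <- X[j, ]
    Aj <- XtWX - w[j] * tcrossprod(xj)
    Ainv[[j]] <- solve(Aj)
    b_loo <- Ainv[[j]] %*% (XtWy - w[j] * xj * beta_out[j])
    mu_loo[j] <- sum(xj * b_loo)
  }
  d_obs <- w * (beta_out - mu_loo)^2
  rss_obs <- sum(d_obs)

  res <- with_seed(seed, {
    BY <- matrix(rnorm(n_sim * k, mean = rep(mu_loo, each = n_sim),
                       sd = rep(se_out, each = n_sim)), n_sim, k)
    M <- BY %*% (w * X)                       # n_sim x p, = X'W y* totals
    D <- matrix(0, n_sim, k)
    for (j in seq_len(k)) {
      xj <- X[j, ]
      Bloo <- (M - w[j] * tcrossprod(BY[, j], xj)) %*% Ainv[[j]]
      fitted_j <- drop(Bloo %*% xj)
      D[, j] <- w[j] * (BY[, j] - fitted_j)^2
    }
    rss_sim <- rowSums(D)
    list(global_p = (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1),
         p_snp = (1 + colSums(D >= rep(d_obs, each = n_sim))) / (n_sim + 1))
  })

  p_bonf <- pmin(1, res$p_snp * k)
  outlier <- p_bonf < outlier_alpha
  corrected <- NULL
  if (any(outlier) && sum(!outlier) > p) {
    corrected <- mvmr_ivw(X[!outlier, , drop = FALSE], beta_out[!outlier],
                          se_out[!outlier])
  }
  structure(list(rss_obs = rss_obs, global_p = res$global_p,
                 outlier_tbl = tibble(snp = snp, residual = d_obs,
                                      pval = res$p_snp, p_bonf = p_bonf,
                                      outlier = outlier),
                 outliers = snp[outlier], corrected = corrected,
                 distortion_p = NA_real_, n_sim = n_sim, seed = seed),
            class = "mr_presso")
}
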