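# Delete-one-block jackknife over contiguous blocks of SNPs.
# stat_fun(idx_keep) must return a numeric scalar.
block_jackknife <- function(n, n_blocks, stat_fun) {
  n_blocks <- min(n_blocks, n)
  bounds <- floor(seq(0, n, length.out = n_blocks + 1))
  est <- vapply(seq_len(n_blocks), function(b) {
    drop_idx <- (bounds[b] + 1):bounds[b + 1]
    stat_fun(setdiff(seq_len(n), drop_idx))
  }, numeric(1))
  sqrt((n_blocks - 1) / n_blocks * sum((est - mean(est))^2))
}

ols_slope <- function(x, y) {
  mx <- mean(x)
  my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) abort("no LD-score variation")
  slope <- sum((x - mx) * (y - my)) / sxx
  c(slope = slope, intercept = my - slope * mx)
}

#' SNP heritability by LD-score regression
#'
#' Regresses per-SNP association chi-squared statistics on `n * l / M`,
#' where `l` is the SNP's LD score and `M` the number of SNPs the
#' heritability is spread over; under the polygenic model
#' `E[chi2] = 1 + n h2 l / M`, so the slope estimates the SNP
#' heritability and the intercept (expected 1 absent confounding) is
#' reported alongside. Unweighted least squares by default (a deliberately
#' didactic divergence from production LD-score software, which iterates
#' heteroskedasticity weights); standard errors come from a
#' delete-one-block jackknife.
#'
#' @param chi2 Per-SNP chi-squared statistics (`z^2`).
#' @param ld Per-SNP LD scores (positive, non-constant).
#' @param n GWAS sample size.
#' @param M Total SNPs represented (`M >= length(chi2)`).
#' @param n_blocks Jackknife blocks (default 200).
#' @return A one-row tibble: `h2`, `h2_se`, `intercept`, `intercept_se`,
#'   `n_snp`.
#' @export
ldsc_h2 <- function(chi2, ld, n, M = length(chi2), n_blocks = 200) {
  stopifnot(length(chi2) == length(ld), all(ld > 0), M >= length(chi2))
  x <- n * ld / M
  fit <- ols_slope(x, chi2)
  h2_se <- block_jackknife(length(x), n_blocks,
                           function(i) ols_slope(x[i], chi2[i])[["slope"]])
  int_se <- block_jackknife(length(x), n_blocks,
                            function(i) ols_slope(x[i], chi2[i])[["intercept"]])
  tibble(h2 = fit[["slope"]], h2_se = h2_se,
         intercept = fit[["intercept"]], intercept_se = int_se,
         n_snp = length(chi2))
}

#' Cross-trait genetic correlation by LD-score regression
#'
#' The slope of the z-score products `z1 * z2` on `sqrt(n1 n2) * l / M`
#' estimates the genetic covariance `rho_g = rg * sqrt(h2_1 h2_2)`; the
#' genetic correlation is that slope normalized by the two heritability
#' estimates from [ldsc_h2()]. No sample-overlap intercept is fitted (the
#' cohorts are assumed disjoint). The jackknife re-estimates the full
#' functional (both heritabilities and the covariance) per deleted block.
#' The reported `rg` is clipped to `[-1.25, 1.25]` with a flag when the
#' raw estimate falls outside `[-1, 1]`.
#'
#' @param z1,z2 Per-SNP z-scores of the two traits.
#' @param ld Per-SNP LD scores.
#' @param n1,n2 The two GWAS sample sizes.
#' @param M Total SNPs represented.
#' @param n_blocks Jackknife blocks.
#' @return A one-row tibble: `rg`, `rg_se`, `rg_p`, `h2_1`, `h2_2`,
#'   `out_of_range` flag, `n_snp`.
#' @export
ldsc_rg <- function(z1, z2, ld, n1, n2, M = length(z1), n_blocks = 200) {
  stopifnot(length(z1) == length(z2), length(z1) == length(ld))
  rg_fun <- function(i) {
    h1 <- ols_slope(n1 * ld[i] / M, z1[i]^2)[["slope"]]
    h2 <- ols_slope(n2 * ld[i] / M, z2[i]^2)[["slope"]]
    rho <- ols_slope(sqrt(n1 * n2) * ld[i] / M, (z1 * z2)[i])[["slope"]]
    if (h1 <= 0 || h2 <= 0) return(NA_real_)
    rho / sqrt(h1 * h2)
  }
  all_idx <- seq_along(z1)
  rg_raw <- rg_fun(all_idx)
  h2_1 <- ols_slope(n1 * ld / M, z1^2)[["slope"]]
  h2_2 <- ols_slope(n2 * ld / M, z2^2)[["slope"]]
  if (is.na(rg_raw)) {
    warn("ldsc_rg: nonpositive heritability estimate, rg undefined")
    return(tibble(rg = NA_real_, rg_se = NA_real_, rg_p = NA_real_,
                  h2_1 = h2_1, h2_2 = h2_2, out_of_range = TRUE,
                  n_snp = length(z1)))
  }
  se <- block_jackknife(length(z1), n_blocks, rg_fun)
  out_of_range <- abs(rg_raw) > 1
  rg <- max(-1.25, min(1.25, rg_raw))
  tibble(rg = rg, rg_se = se, rg_p = 2 * pnorm(-abs(rg_raw / se)),
         h2_1 = h2_1, h2_2 = h2_2, out_of_range = out_of_range,
         n_snp = length(z1))
}
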