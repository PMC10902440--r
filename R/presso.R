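#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Simulation-based detection of horizontal pleiotropy. The observed
#' statistic is the sum of leave-one-out weighted squared residuals of the
#' outcome betas around the IVW fit,
#' `RSS_obs = sum_j w_j (r_j - slope_(-j))^2` with `w_j =
#' beta_exp_j^2/se_out_j^2` and `slope_(-j)` the IVW slope excluding SNP
#' j. Its null distribution is built by redrawing each outcome beta from
#' `Normal(slope_(-j) * beta_exp_j, se_out_j)` `n_sim` times and
#' recomputing the same statistic; the global p-value is the add-one rank
#' of `RSS_obs` among the simulated values (so the smallest attainable p
#' is `1/(n_sim + 1)`). Per-SNP outlier p-values compare each observed
#' leave-one-out residual with its simulated counterparts, Bonferroni
#' corrected across SNPs. When outliers are flagged, the IVW estimate is
#' recomputed without them and a distortion test compares the resulting
#' change in slope against the change produced by removing equally many
#' randomly chosen non-outlying SNPs (reported as informational).
#'
#' @param h A harmonized set with at least 4 SNPs.
#' @param n_sim Number of null simulations (default 1000).
#' @param outlier_alpha Significance level for flagging outliers on the
#'   Bonferroni-corrected per-SNP p-values (default 0.05).
#' @param seed Optional seed; fixed seeds reproduce results bit-exactly.
#' @return An object of class `mr_presso`: a list with `rss_obs`,
#'   `global_p`, `outlier_tbl` (per-SNP residuals and p-values),
#'   `outliers` (flagged SNP ids), `corrected` (outlier-removed IVW
#'   estimate tibble, or `NULL`), `distortion_p`, `n_sim` and `seed`.
#'   [tidy()] returns the per-SNP table, [glance()] the one-row summary.
#' @export
mr_presso <- function(h, n_sim = 1000, outlier_alpha = 0.05, seed = NULL) {
  check_harmonized(h, 4L, "mr_presso")
  k <- nrow(h)
  bx <- h$beta_exp
  byse <- h$se_out
  by <- h$beta_out
  w <- bx^2 / byse^2
  r <- by / bx
  Sw <- sum(w)
  Swr <- sum(w * r)

  loo_slope <- (Swr - w * r) / (Sw - w)
  d_obs <- w * (r - loo_slope)^2
  rss_obs <- sum(d_obs)

  res <- with_seed(seed, {
    mu <- loo_slope * bx
    BY <- matrix(rnorm(n_sim * k, mean = rep(mu, each = n_sim),
                       sd = rep(byse, each = n_sim)), n_sim, k)
    R <- sweep(BY, 2, bx, "/")
    SwrS <- drop(R %*% w)
    L <- (SwrS - sweep(R, 2, w, "*")) / rep(Sw - w, each = n_sim)
    D <- sweep((R - L)^2, 2, w, "*")
    rss_sim <- rowSums(D)
    global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)
    p_snp <- (1 + colSums(D >= rep(d_obs, each = n_sim))) / (n_sim + 1)
    list(global_p = global_p, p_snp = p_snp)
  })

  p_bonf <- pmin(1, res$p_snp * k)
  outlier <- p_bonf < outlier_alpha
  outlier_tbl <- tibble(snp = h$snp, residual = d_obs, pval = res$p_snp,
                        p_bonf = p_bonf, outlier = outlier)

  corrected <- NULL
  distortion_p <- NA_real_
  if (any(outlier) && sum(!outlier) >= 2) {
    corrected <- mr_ivw(h[!outlier, , drop = FALSE], model = "auto")
    slope_full <- sum(w * r) / Sw
    d_slope <- slope_full - corrected$b
    n_out <- sum(outlier)
    keep_idx <- which(!outlier)
    distortion_p <- with_seed(
      if (is.null(seed)) NULL else derive_seed(seed, "distortion"), {
        null_d <- vapply(seq_len(n_sim), function(i) {
          drop_idx <- sample(keep_idx, n_out)
          idx <- setdiff(seq_len(k), drop_idx)
          slope_full - sum(w[idx] * r[idx]) / sum(w[idx])
        }, numeric(1))
        (1 + sum(abs(null_d) >= abs(d_slope))) / (n_sim + 1)
      })
  }

  structure(list(rss_obs = rss_obs, global_p = res$global_p,
                 outlier_tbl = outlier_tbl,
                 outliers = h$snp[outlier], corrected = corrected,
                 distortion_p = distortion_p, n_sim = n_sim, seed = seed),
            class = "mr_presso")
}

#' @method tidy mr_presso
#' @export
tidy.mr_presso <- function(x, ...) x$outlier_tbl

#' @method glance mr_presso
#' @export
glance.mr_presso <- function(x, ...) {
  tibble(rss_obs = x$rss_obs, global_p = x$global_p,
         n_outliers = length(x$outliers),
         b_corrected = if (is.null(x$corrected)) NA_real_ else x$corrected$b[1],
         distortion_p = x$distortion_p, n_sim = x$n_sim)
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO: RSS_obs = %.4g, global p = %.4g (%d sims)\n",
              x$rss_obs, x$global_p, x$n_sim))
  if (length(x$outliers) > 0) {
    cat("Outliers:", paste(x$outliers, collapse = ", "), "\n")
    cat(sprintf("Outlier-corrected IVW slope = %.4g, distortion p = %.3g\n",
                x$corrected$b, x$distortion_p))
  } else {
    cat("No outliers flagged\n")
  }
  invisible(x)
}
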