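#' Per-SNP variance explained from summary statistics
#'
#' The standard summary-statistic approximation
#' `r2 = b^2 2p(1-p) / (b^2 2p(1-p) + se^2 2p(1-p) n)`, symmetric in
#' `eaf` and `1 - eaf` (equivalent to `F/(F + n - 2)` per SNP). An
#' alternative for standardized continuous traits, `2p(1-p) b^2`, is
#' available via `method = "standardized"`.
#'
#' @param beta,se Per-allele effect and its standard error (`se > 0`).
#' @param eaf Effect-allele frequency in `[0, 1]`.
#' @param n GWAS sample size (> 1).
#' @param method `"approx"` (default) or `"standardized"`.
#' @return A numeric vector of per-SNP r-squared values. Monomorphic SNPs
#'   (`eaf` 0 or 1) return 0 with a warning.
#' @export
#' @examples
#' variance_explained(0.1, 0.02, 0.3, 18340)
variance_explained <- function(beta, se, eaf, n,
                               method = c("approx", "standardized")) {
  method <- match.arg(method)
  stopifnot(all(se > 0), all(n > 1))
  het <- 2 * eaf * (1 - eaf)
  mono <- het == 0
  if (any(mono)) warn("variance_explained: monomorphic SNP(s), r2 set to 0")
  r2 <- switch(method,
    approx = (beta^2 * het) / (beta^2 * het + se^2 * het * n),
    standardized = het * beta^2)
  r2[mono] <- 0
  r2
}

#' Instrument-strength F-statistic
#'
#' `F = (r2 / (1 - r2)) * ((n - k - 1) / k)` for `k` instruments jointly
#' explaining `r2` of the exposure in a GWAS of size `n`. Values below 10
#' conventionally flag weak-instrument bias.
#'
#' @param total_r2 Total variance explained, in `[0, 1)`.
#' @param n Exposure GWAS sample size.
#' @param k Number of instruments (`n > k + 1`).
#' @return The F-statistic.
#' @export
#' @examples
#' f_statistic(0.02, 1000, 1)  # 20.367...
f_statistic <- function(total_r2, n, k) {
  stopifnot(all(total_r2 >= 0), all(total_r2 < 1), all(k >= 1))
  if (any(n <= k + 1)) abort("f_statistic requires n > k + 1")
  (total_r2 / (1 - total_r2)) * ((n - k - 1) / k)
}

#' Select instruments: significance, MAF and LD-clump cascade
#'
#' Applies the instrument-selection cascade to an exposure summary set:
#' keep SNPs with `pval < p_threshold` and minor allele frequency at least
#' `maf_min`, then prune correlated SNPs so that at most one SNP (the one
#' with the smallest p-value) survives per LD cluster. Correlation is
#' supplied explicitly rather than computed from genotypes: either a
#' `ld_cluster` column / vector of cluster tags, or a pairwise
#' `(snp_a, snp_b, r2)` table whose pairs with `r2 > clump_r2` are linked
#' into clusters.
#'
#' @param stats Summary-statistic tibble (canonical columns).
#' @param p_threshold Genome-wide instrument threshold (default 1e-5, the
#'   relaxed threshold conventional for microbiome/metabolite exposures).
#' @param clump_r2,clump_kb Clumping parameters (defaults 0.001 and
#'   10,000 kb). `clump_r2` thresholds the pairwise LD table; `clump_kb`
#'   is carried in the filter report for provenance (positional pruning
#'   requires coordinates, which summary tables here do not carry).
#' @param maf_min Minimum minor allele frequency (default 0.01).
#' @param ld_clusters Optional cluster tags (vector parallel to `stats`
#'   rows) or a pairwise LD data frame with columns `snp_a`, `snp_b`,
#'   `r2`. Defaults to the `ld_cluster` column of `stats` when present,
#'   otherwise all SNPs are treated as independent.
#'
#' @return The surviving rows of `stats`, with a stage-count filter report
#'   attached as the `"filter_report"` attribute (see [filter_report()])
#'   and per-SNP drop reasons as `"drops"`. No SNP passing is an empty
#'   result, not an error.
#' @export
select_instruments <- function(stats, p_threshold = 1e-5, clump_r2 = 0.001,
                               clump_kb = 10000, maf_min = 0.01,
                               ld_clusters = NULL) {
  stopifnot(p_threshold > 0, maf_min >= 0, clump_r2 > 0, clump_kb > 0)
  drops <- tibble(snp = character(), reason = character())
  report <- tibble(filter = character(), n_before = integer(),
                   n_after = integer())
  log_stage <- function(name, before, after) {
    report <<- bind_rows(report, tibble(filter = name,
                                        n_before = nrow(before),
                                        n_after = nrow(after)))
  }

  if (is.null(ld_clusters) && "ld_cluster" %in% names(stats)) {
    ld_clusters <- stats$ld_cluster
  }
  if (!is.null(ld_clusters) && !is.data.frame(ld_clusters)) {
    stopifnot(length(ld_clusters) == nrow(stats))
    stats$.cluster <- as.character(ld_clusters)
    # missing tags mean "no LD information": treat as independent
    stats$.cluster[is.na(stats$.cluster)] <-
      stats$snp[is.na(stats$.cluster)]
  } else if (is.data.frame(ld_clusters)) {
    stopifnot(all(c("snp_a", "snp_b", "r2") %in% names(ld_clusters)))
    stats$.cluster <- pairwise_ld_clusters(stats$snp, ld_clusters, clump_r2)
  } else {
    stats$.cluster <- stats$snp
  }

  s0 <- stats
  s1 <- filter(s0, .data$pval < p_threshold)
  drops <- bind_rows(drops, tibble(snp = setdiff(s0$snp, s1$snp),
                                   reason = "above p_threshold"))
  log_stage(sprintf("pval<%g", p_threshold), s0, s1)

  s2 <- filter(s1, pmin(.data$eaf, 1 - .data$eaf) >= maf_min)
  drops <- bind_rows(drops, tibble(snp = setdiff(s1$snp, s2$snp),
                                   reason = sprintf("MAF<%g", maf_min)))
  log_stage(sprintf("MAF>=%g", maf_min), s1, s2)

  s3 <- s2 |>
    arrange(.data$.cluster, .data$pval, .data$snp) |>
    distinct(.data$.cluster, .keep_all = TRUE) |>
    arrange(match(.data$snp, s2$snp))
  drops <- bind_rows(drops, tibble(snp = setdiff(s2$snp, s3$snp),
                                   reason = "clumped"))
  log_stage(sprintf("clump r2>%g within %gkb", clump_r2, clump_kb), s2, s3)

  out <- select(s3, -".cluster")
  attr(out, "filter_report") <- report
  attr(out, "drops") <- drops
  out
}

# Link SNPs sharing r2 > threshold into connected components (union-find).
pairwise_ld_clusters <- function(snps, ld_table, clump_r2) {
  parent <- seq_along(snps)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  keep <- ld_table$r2 > clump_r2
  ia <- match(ld_table$snp_a[keep], snps)
  ib <- match(ld_table$snp_b[keep], snps)
  ok <- !is.na(ia) & !is.na(ib)
  for (j in which(ok)) {
    ra <- find(ia[j]); rb <- find(ib[j])
    if (ra != rb) parent[rb] <- ra
  }
  as.character(vapply(seq_along(snps), find, integer(1)))
}

#' Stage-count report of an instrument-selection run
#'
#' @param x The tibble returned by [select_instruments()].
#' @return A tibble with columns `filter`, `n_before`, `n_after` (the
#'   `n_after` of each stage equals the `n_before` of the next).
#' @export
filter_report <- function(x) {
  attr(x, "filter_report") %||%
    tibble(filter = character(), n_before = integer(), n_after = integer())
}

#' Instrument strength and count gates
#'
#' Evaluates the three exposure-level gates applied after instrument
#' selection: joint F-statistic at least `f_min`, total variance explained
#' at least `r2_min`, and at least `k_min` instruments. All three are
#' always evaluated and reported.
#'
#' @param instruments Instrument tibble (canonical columns).
#' @param n Exposure GWAS sample size; defaults to the largest `n` among
#'   the instruments.
#' @param f_min,r2_min,k_min Gate thresholds (defaults 10, 0.005, 3).
#' @return A one-row tibble with `k`, `total_r2`, `f_stat`, a logical
#'   `pass`, and a `reasons` string listing every failed gate (empty when
#'   passing).
#' @export
strength_gates <- function(instruments, n = NULL, f_min = 10,
                           r2_min = 0.005, k_min = 3) {
  k <- nrow(instruments)
  n <- n %||% (if (k > 0) max(instruments$n) else NA_real_)
  total_r2 <- if (k > 0) {
    sum(variance_explained(instruments$beta, instruments$se,
                           instruments$eaf, instruments$n))
  } else 0
  f <- if (k >= 1 && !is.na(n) && n > k + 1) f_statistic(total_r2, n, k) else 0
  reasons <- c(
    if (k < k_min) sprintf("fewer than %d SNPs", k_min),
    if (total_r2 < r2_min)
      sprintf("variance explained < %s%%", format(100 * r2_min)),
    if (f < f_min) sprintf("F < %g", f_min))
  tibble(k = k, total_r2 = total_r2, f_stat = f,
         pass = length(reasons) == 0,
         reasons = paste(reasons, collapse = "; "))
}

#' Statistical power for MR with a binary outcome
#'
#' Closed-form normal-approximation power of the two-sided IVW test at
#' level `alpha` for detecting an odds ratio `or_alt` per SD of exposure,
#' given instruments explaining `total_r2` of the exposure and an outcome
#' GWAS of `n` subjects with case fraction `case_frac`. The non-centrality
#' is `lambda = n * total_r2 * log(or_alt)^2 * case_frac * (1 - case_frac)`
#' and power is `pnorm(-z + sqrt(lambda)) + pnorm(-z - sqrt(lambda))` with
#' `z = qnorm(1 - alpha/2)`. The formula is validated against a
#' Monte-Carlo rejection-rate oracle in the test suite rather than trusted
#' blindly.
#'
#' @param n Outcome GWAS sample size.
#' @param case_frac Case fraction in (0, 1).
#' @param total_r2 Instrument variance explained in the exposure.
#' @param or_alt Detectable odds ratio (> 0); `or_alt = 1` returns `alpha`.
#' @param alpha Two-sided test size (default 0.05).
#' @return Power in `[0, 1]`.
#' @export
mr_power <- function(n, case_frac, total_r2, or_alt, alpha = 0.05) {
  stopifnot(or_alt > 0, case_frac > 0, case_frac < 1,
            total_r2 >= 0, alpha > 0, alpha < 1)
  z <- qnorm(1 - alpha / 2)
  lambda <- n * total_r2 * log(or_alt)^2 * case_frac * (1 - case_frac)
  pnorm(-z + sqrt(lambda)) + pnorm(-z - sqrt(lambda))
}
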