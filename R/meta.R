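#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement, mapped back to the
#' input order (a thin validated wrapper over [stats::p.adjust()]).
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, same length and order as the input.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bh_fdr <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(!is.finite(pvals) | pvals <= 0 | pvals > 1)) {
    abort("bh_fdr: p-values must lie in (0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Recover the log-OR standard error from a printed OR and 95% CI
#'
#' `se = (log(ci_high) - log(ci_low)) / (2 * 1.96)`. Published tables give
#' ORs with confidence intervals but no standard errors; this converts
#' them for meta-analysis. A warning is raised when the CI is asymmetric
#' on the log scale by more than 10% (a sign of heavy rounding in the
#' printed values).
#'
#' @param or_point Odds ratio point estimate.
#' @param ci_low,ci_high 95% CI bounds, `0 < ci_low <= or_point <= ci_high`.
#' @return Standard error(s) of the log odds ratio.
#' @export
#' @examples
#' ci_to_se(0.62, 0.44, 0.88)  # ~0.1768
ci_to_se <- function(or_point, ci_low, ci_high) {
  if (any(!(ci_low > 0 & ci_low <= or_point & or_point <= ci_high))) {
    abort("ci_to_se: need 0 < ci_low <= or_point <= ci_high")
  }
  up <- log(ci_high) - log(or_point)
  dn <- log(or_point) - log(ci_low)
  asym <- abs(up - dn) / pmax((up + dn) / 2, .Machine$double.eps)
  if (any(asym > 0.10)) {
    warn(sprintf("ci_to_se: CI asymmetric on the log scale (max %.0f%%); printed values may be heavily rounded",
                 100 * max(asym)))
  }
  (log(ci_high) - log(ci_low)) / (2 * qnorm(0.975))
}

#' Inverse-variance meta-analysis of replication cohorts
#'
#' Pools per-study log odds ratios with fixed-effect weights `1/se^2` or
#' DerSimonian-Laird random-effects weights `1/(se^2 + tau2)` where
#' `tau2 = max(0, (Q - df) / C)` and `C = sum(w) - sum(w^2)/sum(w)`.
#' Cochran's Q and `tau2` are always reported; when `Q <= df` the
#' random-effects model reduces exactly to the fixed-effect one.
#'
#' @param studies Data frame with columns `beta` and `se` (log-OR scale),
#'   or columns `or`, `ci_low`, `ci_high` which are converted via
#'   [ci_to_se()]. A single study is returned unchanged with a warning.
#' @param model `"fixed"` or `"dl_random"`.
#' @return A one-row tibble: `model`, `k`, `b`, `se`, `pval`, `or`,
#'   `or_lo`, `or_hi`, `Q`, `q_pval`, `tau2`; normalized per-study weights
#'   in the `"weights"` attribute.
#' @export
#' @examples
#' tab <- tibble::tibble(or = c(0.62, 0.37), ci_low = c(0.44, 0.14),
#'                       ci_high = c(0.88, 0.93))
#' mr_meta(tab, model = "fixed")  # pooled OR ~0.58 (0.42, 0.81)
mr_meta <- function(studies, model = c("fixed", "dl_random")) {
  model <- match.arg(model)
  stopifnot(is.data.frame(studies))
  if (!all(c("beta", "se") %in% names(studies))) {
    if (all(c("or", "ci_low", "ci_high") %in% names(studies))) {
      studies$beta <- log(studies$or)
      studies$se <- ci_to_se(studies$or, studies$ci_low, studies$ci_high)
    } else {
      abort("mr_meta: need columns beta+se or or+ci_low+ci_high")
    }
  }
  th <- studies$beta
  se <- studies$se
  stopifnot(all(se > 0))
  k <- length(th)
  if (k < 1) abort("mr_meta: no studies")
  ci <- qnorm(0.975)
  if (k == 1) {
    warn("mr_meta: single study, returned unchanged")
    out <- tibble(model = model, k = 1L, b = th, se = se,
                  pval = 2 * pnorm(-abs(th / se)), or = exp(th),
                  or_lo = exp(th - ci * se), or_hi = exp(th + ci * se),
                  Q = 0, q_pval = NA_real_, tau2 = 0)
    attr(out, "weights") <- 1
    return(out)
  }
  w <- 1 / se^2
  pooled_f <- sum(w * th) / sum(w)
  Q <- sum(w * (th - pooled_f)^2)
  df <- k - 1L
  tau2 <- 0
  if (model == "dl_random") {
    C <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (Q - df) / C)
    w <- 1 / (se^2 + tau2)
  }
  b <- sum(w * th) / sum(w)
  se_p <- 1 / sqrt(sum(w))
  out <- tibble(model = model, k = k, b = b, se = se_p,
                pval = 2 * pnorm(-abs(b / se_p)), or = exp(b),
                or_lo = exp(b - ci * se_p), or_hi = exp(b + ci * se_p),
                Q = Q, q_pval = pchisq(Q, df, lower.tail = FALSE),
                tau2 = tau2)
  attr(out, "weights") <- w / sum(w)
  out
}
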