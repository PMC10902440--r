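# ---- fast numeric cores ----------------------------------------------------
# All estimators operate on aligned vectors; the tibble-facing wrappers
# below add validation, OR/CI columns and class attributes.

.wald <- function(bx, by, byse) {
  list(b = by / bx, se = byse / abs(bx))
}

.ivw <- function(bx, by, byse, model = "auto") {
  k <- length(bx)
  w <- bx^2 / byse^2
  r <- by / bx
  b <- sum(w * r) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  Q <- sum(w * (r - b)^2)
  df <- k - 1L
  q_pval <- if (df > 0) pchisq(Q, df, lower.tail = FALSE) else NA_real_
  used <- if (model == "auto") {
    if (!is.na(q_pval) && q_pval < 0.05) "random" else "fixed"
  } else model
  se <- if (used == "random" && df > 0) {
    se_fixed * max(1, sqrt(Q / df))
  } else se_fixed
  list(b = b, se = se, pval = 2 * pnorm(-abs(b / se)), k = k,
       model = used, Q = Q, df = df, q_pval = q_pval)
}

.egger <- function(bx, bxse, by, byse) {
  k <- length(bx)
  s <- ifelse(bx < 0, -1, 1)  # orient so all exposure betas >= 0
  x <- bx * s
  y <- by * s
  w <- 1 / byse^2
  fit <- lm(y ~ x, weights = w)
  sm <- summary(fit)
  disp <- max(1, sm$sigma)  # multiplicative over-dispersion, floored at 1
  co <- sm$coefficients
  b <- co["x", "Estimate"]
  b_se <- co["x", "Std. Error"] / sm$sigma * disp
  i <- co["(Intercept)", "Estimate"]
  i_se <- co["(Intercept)", "Std. Error"] / sm$sigma * disp
  df <- k - 2L
  Q <- sum(w * fit$residuals^2)
  list(b = b, se = b_se, pval = 2 * pt(-abs(b / b_se), df),
       intercept = i, intercept_se = i_se,
       intercept_pval = 2 * pt(-abs(i / i_se), df),
       k = k, Q = Q, df = df,
       q_pval = if (df > 0) pchisq(Q, df, lower.tail = FALSE) else NA_real_)
}

# Bowden-style weighted median with cumulative-weight midpoint
# interpolation; ties broken by the first crossing.
.weighted_median <- function(r, w) {
  o <- order(r)
  r <- r[o]
  w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(r[1])
  below <- max(which(s < 0.5))
  if (below == length(r)) return(r[length(r)])
  r[below] + (r[below + 1] - r[below]) * (0.5 - s[below]) /
    (s[below + 1] - s[below])
}

# Kernel-smoothed mode of the Wald ratios (normal kernel, modified
# Silverman bandwidth as in the mode-based estimator literature).
.mode_point <- function(r, w, bandwidth_factor = 1) {
  w <- w / sum(w)
  spread <- min(sd(r), mad(r))
  if (!is.finite(spread) || spread == 0) return(r[which.max(w)])
  h <- bandwidth_factor * 0.9 * spread * length(r)^(-1 / 5)
  d <- density(r, weights = w, bw = h, n = 1024)
  d$x[which.max(d$y)]
}

# Parametric bootstrap SE: redraw betas from their sampling distributions
# and recompute the point estimator.
.boot_se <- function(bx, bxse, by, byse, n_boot, point_fun) {
  k <- length(bx)
  est <- vapply(seq_len(n_boot), function(i) {
    bxs <- rnorm(k, bx, bxse)
    bys <- rnorm(k, by, byse)
    point_fun(bxs, bys)
  }, numeric(1))
  sd(est)
}

# ---- user-facing estimators ------------------------------------------------

check_harmonized <- function(h, min_snp, caller) {
  need <- c("beta_exp", "se_exp", "beta_out", "se_out")
  missing <- setdiff(need, names(h))
  if (length(missing) > 0) {
    abort(paste0(caller, ": missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(h) < min_snp) {
    abort(sprintf("%s requires at least %d SNPs (got %d)",
                  caller, min_snp, nrow(h)))
  }
  if (any(h$beta_exp == 0)) abort(paste0(caller, ": null instrument (beta_exp = 0)"))
  invisible(h)
}

estimate_row <- function(method, b, se, pval, n_snp, model = NA_character_) {
  ci <- qnorm(0.975)
  tibble(method = method, n_snp = n_snp, b = b, se = se, pval = pval,
         or = exp(b), or_lo = exp(b - ci * se), or_hi = exp(b + ci * se),
         model = model)
}

#' Per-SNP Wald ratio estimate
#'
#' The single-instrument causal estimate `beta_out / beta_exp` with
#' first-order delta-method standard error `se_out / |beta_exp|`.
#'
#' @param beta_exp,se_exp Exposure effect and SE (SE unused by the
#'   first-order SE but kept in the signature for the second-order
#'   variant).
#' @param beta_out,se_out Outcome effect and SE.
#' @param second_order Use the second-order delta-method SE
#'   `sqrt(se_out^2/beta_exp^2 + beta_out^2 se_exp^2 / beta_exp^4)`.
#' @return A tibble with columns `ratio` and `se`.
#' @export
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out,
                       second_order = FALSE) {
  if (any(beta_exp == 0)) abort("null instrument (beta_exp = 0)")
  se <- if (second_order) {
    sqrt(se_out^2 / beta_exp^2 + beta_out^2 * se_exp^2 / beta_exp^4)
  } else {
    abs(se_out / beta_exp)
  }
  tibble(ratio = beta_out / beta_exp, se = se)
}

#' Inverse-variance weighted estimate
#'
#' The weighted average of per-SNP Wald ratios with weights
#' `beta_exp^2 / se_out^2` (equivalently, weighted regression of outcome
#' betas on exposure betas through the origin). The fixed-effect SE is
#' `1/sqrt(sum(w))`; the random-effects (multiplicative over-dispersion)
#' SE inflates it by `max(1, sqrt(Q/df))`. With `model = "auto"` the
#' random-effects model is used when Cochran's Q heterogeneity p-value is
#' below 0.05 and the fixed-effect model otherwise.
#'
#' @param h A harmonized set (see [harmonize()] / [as_harmonized()]) with
#'   at least 2 SNPs (1 allowed under `model = "fixed"`, where the result
#'   degenerates to the Wald ratio).
#' @param model `"auto"`, `"fixed"` or `"random"`.
#' @return A one-row tibble (`method`, `n_snp`, `b`, `se`, `pval`, `or`,
#'   `or_lo`, `or_hi`, `model`) with Cochran's Q statistics in the
#'   `"heterogeneity"` attribute.
#' @export
mr_ivw <- function(h, model = c("auto", "fixed", "random")) {
  model <- match.arg(model)
  check_harmonized(h, if (model == "fixed") 1L else 2L, "mr_ivw")
  f <- .ivw(h$beta_exp, h$beta_out, h$se_out, model)
  out <- estimate_row("IVW", f$b, f$se, f$pval, f$k, f$model)
  attr(out, "heterogeneity") <- tibble(method = "IVW", Q = f$Q, df = f$df,
                                       q_pval = f$q_pval)
  out
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome betas on exposure betas with an
#' unconstrained intercept (weights `1/se_out^2`), after orienting inputs
#' so all exposure betas are non-negative. The intercept estimates the
#' average direct (pleiotropic) effect; its t-test (df = n - 2) is the
#' Egger intercept pleiotropy test, also available via
#' [mr_pleiotropy_test()]. Standard errors use multiplicative
#' over-dispersion floored at 1.
#'
#' @inheritParams mr_ivw
#' @return A one-row estimate tibble with `"intercept"` (estimate/SE/p)
#'   and `"heterogeneity"` attributes.
#' @export
mr_egger <- function(h) {
  check_harmonized(h, 3L, "mr_egger")
  f <- .egger(h$beta_exp, h$se_exp, h$beta_out, h$se_out)
  out <- estimate_row("MR Egger", f$b, f$se, f$pval, f$k)
  attr(out, "intercept") <- tibble(intercept = f$intercept,
                                   se = f$intercept_se,
                                   pval = f$intercept_pval)
  attr(out, "heterogeneity") <- tibble(method = "MR Egger", Q = f$Q,
                                       df = f$df, q_pval = f$q_pval)
  out
}

#' Weighted median estimate
#'
#' The inverse-variance weighted median of the Wald ratios (cumulative
#' weight interpolated at 0.5), consistent when at least half the weight
#' comes from valid instruments. The SE is a parametric bootstrap: betas
#' are redrawn from their sampling distributions and the weighted median
#' recomputed `n_boot` times.
#'
#' @inheritParams mr_ivw
#' @param n_boot Bootstrap replicates for the SE; `0` skips the bootstrap
#'   (point estimate only, `se`/`pval` set to `NA`).
#' @param seed Optional seed for the bootstrap.
#' @return A one-row estimate tibble.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = NULL) {
  check_harmonized(h, 3L, "mr_weighted_median")
  r <- h$beta_out / h$beta_exp
  w <- h$beta_exp^2 / h$se_out^2
  b <- .weighted_median(r, w)
  if (n_boot > 0) {
    se <- with_seed(seed, .boot_se(h$beta_exp, h$se_exp, h$beta_out,
                                   h$se_out, n_boot, function(bx, by) {
      .weighted_median(by / bx, bx^2 / h$se_out^2)
    }))
    estimate_row("Weighted median", b, se, 2 * pnorm(-abs(b / se)), nrow(h))
  } else {
    estimate_row("Weighted median", b, NA_real_, NA_real_, nrow(h))
  }
}

mr_mode_impl <- function(h, kind, n_boot, seed, bandwidth_factor, label) {
  check_harmonized(h, 3L, label)
  r <- h$beta_out / h$beta_exp
  se_r <- h$se_out / abs(h$beta_exp)
  w <- if (kind == "weighted") 1 / se_r^2 else rep(1, nrow(h))
  b <- .mode_point(r, w, bandwidth_factor)
  if (n_boot > 0) {
    se <- with_seed(seed, .boot_se(h$beta_exp, h$se_exp, h$beta_out,
                                   h$se_out, n_boot, function(bx, by) {
      rs <- by / bx
      ws <- if (kind == "weighted") bx^2 / h$se_out^2 else rep(1, length(bx))
      .mode_point(rs, ws, bandwidth_factor)
    }))
    estimate_row(label, b, se, 2 * pnorm(-abs(b / se)), nrow(h))
  } else {
    estimate_row(label, b, NA_real_, NA_real_, nrow(h))
  }
}

#' Mode-based estimates
#'
#' The mode of the normal-kernel smoothed density of Wald ratios: the
#' causal effect of the largest cluster of SNPs with similar ratios.
#' `mr_weighted_mode()` weights SNPs by inverse Wald-ratio variance;
#' `mr_simple_mode()` weights uniformly. Bandwidth follows the modified
#' Silverman rule (`0.9 min(sd, mad) n^(-1/5)`) scaled by
#' `bandwidth_factor`. SEs are parametric bootstrap as in
#' [mr_weighted_median()].
#'
#' @inheritParams mr_weighted_median
#' @param bandwidth_factor Multiplier on the Silverman bandwidth.
#' @return A one-row estimate tibble.
#' @export
mr_weighted_mode <- function(h, n_boot = 1000, seed = NULL,
                             bandwidth_factor = 1) {
  mr_mode_impl(h, "weighted", n_boot, seed, bandwidth_factor, "Weighted mode")
}

#' @rdname mr_weighted_mode
#' @export
mr_simple_mode <- function(h, n_boot = 1000, seed = NULL,
                           bandwidth_factor = 1) {
  mr_mode_impl(h, "simple", n_boot, seed, bandwidth_factor, "Simple mode")
}

#' Run all five MR estimators
#'
#' @inheritParams mr_weighted_median
#' @param model IVW model rule (see [mr_ivw()]).
#' @return A five-row tibble, one row per method.
#' @export
mr_all <- function(h, model = "auto", n_boot = 1000, seed = NULL) {
  seeds <- if (is.null(seed)) list(NULL, NULL, NULL) else
    lapply(c("wm", "wmode", "smode"), function(k) derive_seed(seed, k))
  bind_rows(
    mr_ivw(h, model = model),
    mr_egger(h),
    mr_weighted_median(h, n_boot = n_boot, seed = seeds[[1]]),
    mr_weighted_mode(h, n_boot = n_boot, seed = seeds[[2]]),
    mr_simple_mode(h, n_boot = n_boot, seed = seeds[[3]])
  )
}

#' Cochran's Q heterogeneity for IVW and MR-Egger
#'
#' @inheritParams mr_ivw
#' @return A two-row tibble (`method`, `Q`, `df`, `q_pval`) with
#'   df = n - 1 for IVW and n - 2 for Egger.
#' @export
mr_heterogeneity <- function(h) {
  check_harmonized(h, 3L, "mr_heterogeneity")
  bind_rows(attr(mr_egger(h), "heterogeneity"),
            attr(mr_ivw(h), "heterogeneity"))
}

#' Egger intercept test for directional pleiotropy
#'
#' @inheritParams mr_ivw
#' @return A one-row tibble (`intercept`, `se`, `pval`); p < 0.05 flags
#'   directional horizontal pleiotropy.
#' @export
mr_pleiotropy_test <- function(h) {
  check_harmonized(h, 3L, "mr_pleiotropy_test")
  attr(mr_egger(h), "intercept")
}

# ---- fitted-object surface -------------------------------------------------

#' Fit the full estimator battery on a harmonized set
#'
#' Bundles the five estimators, heterogeneity statistics and the Egger
#' intercept into one fitted object with [tidy()], [glance()] and
#' [autoplot()] methods.
#'
#' @inheritParams mr_all
#' @return An object of class `mr_fit`.
#' @export
mr_fit <- function(h, model = "auto", n_boot = 1000, seed = NULL) {
  structure(list(estimates = mr_all(h, model, n_boot, seed),
                 heterogeneity = mr_heterogeneity(h),
                 pleiotropy = mr_pleiotropy_test(h),
                 data = h),
            class = "mr_fit")
}

#' @method tidy mr_fit
#' @export
tidy.mr_fit <- function(x, ...) x$estimates

#' @method glance mr_fit
#' @export
glance.mr_fit <- function(x, ...) {
  ivw <- x$estimates[x$estimates$method == "IVW", ]
  qi <- x$heterogeneity[x$heterogeneity$method == "IVW", ]
  qe <- x$heterogeneity[x$heterogeneity$method == "MR Egger", ]
  tibble(n_snp = ivw$n_snp, b_ivw = ivw$b, pval_ivw = ivw$pval,
         model_ivw = ivw$model,
         Q_ivw = qi$Q, q_pval_ivw = qi$q_pval,
         Q_egger = qe$Q, q_pval_egger = qe$q_pval,
         egger_intercept = x$pleiotropy$intercept,
         intercept_pval = x$pleiotropy$pval)
}

#' @export
print.mr_fit <- function(x, ...) {
  cat("Two-sample MR fit,", nrow(x$data), "SNPs\n")
  print(x$estimates)
  cat(sprintf("Egger intercept %.4f (p = %.3g)\n",
              x$pleiotropy$intercept, x$pleiotropy$pval))
  invisible(x)
}
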