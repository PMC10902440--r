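#' Steiger directionality test
#'
#' Compares the instrument-explained variance on the exposure and outcome
#' sides. Causality in the expected direction (exposure to outcome) is
#' supported when the instruments explain more variance in the exposure.
#' The p-value is an asymptotic two-sample z-test on the difference of the
#' Fisher-z-transformed correlations `sqrt(r2)` with the respective sample
#' sizes (the two GWAS are assumed non-overlapping).
#'
#' @param h A harmonized set.
#' @param n_exp,n_out Sample sizes (> 3); default to the `n_exp`/`n_out`
#'   columns of `h` when present.
#' @return A one-row tibble: `r2_exposure`, `r2_outcome`, `direction`
#'   (TRUE when `r2_exposure > r2_outcome`), `steiger_p`.
#' @export
mr_steiger <- function(h, n_exp = NULL, n_out = NULL) {
  check_harmonized(h, 1L, "mr_steiger")
  n_exp <- n_exp %||% (if ("n_exp" %in% names(h)) h$n_exp)
  n_out <- n_out %||% (if ("n_out" %in% names(h)) h$n_out)
  if (is.null(n_exp) || is.null(n_out)) {
    abort("mr_steiger: supply n_exp and n_out (not found in h)")
  }
  stopifnot(all(n_exp > 3), all(n_out > 3))
  eaf <- if ("eaf" %in% names(h)) h$eaf else rep(0.5, nrow(h))
  r2e <- sum(variance_explained(h$beta_exp, h$se_exp, eaf, n_exp))
  r2o <- sum(variance_explained(h$beta_out, h$se_out, eaf, n_out))
  ne <- max(n_exp)
  no <- max(n_out)
  z <- (atanh(sqrt(r2e)) - atanh(sqrt(r2o))) /
    sqrt(1 / (ne - 3) + 1 / (no - 3))
  tibble(r2_exposure = r2e, r2_outcome = r2o,
         direction = r2e > r2o, steiger_p = 2 * pnorm(-abs(z)))
}

#' Per-SNP Steiger filtering
#'
#' Drops SNPs whose per-SNP variance explained in the outcome exceeds that
#' in the exposure (variants suggesting reverse causation); the exclusion
#' log records them with reason `"steiger"`.
#'
#' @inheritParams mr_steiger
#' @return The filtered harmonized set (never larger than the input).
#' @export
steiger_filter <- function(h, n_exp = NULL, n_out = NULL) {
  check_harmonized(h, 1L, "steiger_filter")
  n_exp <- n_exp %||% (if ("n_exp" %in% names(h)) h$n_exp)
  n_out <- n_out %||% (if ("n_out" %in% names(h)) h$n_out)
  eaf <- if ("eaf" %in% names(h)) h$eaf else rep(0.5, nrow(h))
  r2e <- variance_explained(h$beta_exp, h$se_exp, eaf, n_exp)
  r2o <- variance_explained(h$beta_out, h$se_out, eaf, n_out)
  drop <- r2o > r2e
  out <- h[!drop, , drop = FALSE]
  attr(out, "exclusions") <- bind_rows(
    exclusions(h), tibble(snp = h$snp[drop],
                          reason = rep("steiger", sum(drop))))
  out
}

#' Reverse-direction MR
#'
#' Runs the identical selection + harmonization + estimation pipeline with
#' the roles swapped: the original outcome becomes the exposure. Because
#' disease outcomes need genome-wide significant instruments, selection
#' uses its own (stricter) threshold, default 5e-8. Fewer than 3 surviving
#' instruments is reported as "not testable" rather than an error.
#'
#' @param outcome_stats Summary statistics of the original outcome (now
#'   instrumented as the exposure).
#' @param exposure_stats Summary statistics of the original exposure (now
#'   the outcome).
#' @param p_threshold Instrument threshold for the reverse direction.
#' @param maf_min,ld_clusters Passed to [select_instruments()].
#' @param palindrome_band Passed to [harmonize()].
#' @param n_boot,seed Passed to [mr_all()].
#' @return A list of class `mr_reverse`: `testable`, `k`, and (when
#'   testable) `estimates` (the [mr_all()] table labelled
#'   `direction = "reverse"`) and the harmonized set.
#' @export
reverse_mr <- function(outcome_stats, exposure_stats, p_threshold = 5e-8,
                       maf_min = 0.01, ld_clusters = NULL,
                       palindrome_band = 0.08, n_boot = 1000, seed = NULL) {
  iv <- select_instruments(outcome_stats, p_threshold = p_threshold,
                           maf_min = maf_min, ld_clusters = ld_clusters)
  if (nrow(iv) < 3) {
    return(structure(list(testable = FALSE, k = nrow(iv), estimates = NULL),
                     class = "mr_reverse"))
  }
  h <- harmonize(iv, exposure_stats, palindrome_band = palindrome_band)
  if (nrow(h) < 3) {
    return(structure(list(testable = FALSE, k = nrow(h), estimates = NULL),
                     class = "mr_reverse"))
  }
  est <- mr_all(h, n_boot = n_boot, seed = seed)
  est$direction <- "reverse"
  structure(list(testable = TRUE, k = nrow(h), estimates = est, data = h),
            class = "mr_reverse")
}

#' @export
print.mr_reverse <- function(x, ...) {
  if (!x$testable) {
    cat("Reverse MR: not testable (", x$k, "instruments )\n")
  } else {
    cat("Reverse MR (", x$k, "instruments ):\n")
    print(x$estimates)
  }
  invisible(x)
}
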