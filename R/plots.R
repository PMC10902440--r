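#' Scatter plot of a fitted MR analysis
#'
#' Outcome betas against exposure betas with per-SNP error bars, overlaid
#' with the IVW and MR-Egger fitted lines.
#'
#' @param object An [mr_fit()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mr_fit
#' @export
autoplot.mr_fit <- function(object, ...) {
  h <- object$data
  est <- object$estimates
  ivw_b <- est$b[est$method == "IVW"]
  egg_b <- est$b[est$method == "MR Egger"]
  egg_a <- object$pleiotropy$intercept
  s <- ifelse(h$beta_exp < 0, -1, 1)
  df <- tibble(bx = h$beta_exp * s, by = h$beta_out * s,
               bxse = h$se_exp, byse = h$se_out)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bx, y = .data$by)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$by - .data$byse,
                                        ymax = .data$by + .data$byse),
                           linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$bx - .data$bxse,
                                         xmax = .data$bx + .data$bxse),
                            linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::geom_abline(intercept = 0, slope = ivw_b,
                         colour = "#2166ac") +
    ggplot2::geom_abline(intercept = egg_a, slope = egg_b,
                         colour = "#b2182c", linetype = 2) +
    ggplot2::labs(x = "SNP effect on exposure",
                  y = "SNP effect on outcome",
                  caption = "solid: IVW; dashed: MR-Egger") +
    ggplot2::theme_minimal()
}

#' Forest plot of MR estimates
#'
#' @param estimates An estimate tibble (e.g. from [mr_all()] or the
#'   pipeline `estimates` table) with `or`, `or_lo`, `or_hi` and a label
#'   column.
#' @param label Column used for row labels (default `method`, or
#'   `exposure` when present).
#' @return A ggplot on the log-OR axis.
#' @export
plot_forest <- function(estimates, label = NULL) {
  label <- label %||% if ("exposure" %in% names(estimates)) "exposure" else
    "method"
  df <- mutate(estimates, .label = .data[[label]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$or, y = .data$.label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 3) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$or_lo,
                                         xmax = .data$or_hi),
                            height = 0.2) +
    ggplot2::geom_point(shape = 15, size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Volcano plot of per-exposure IVW results
#'
#' @param summary The pipeline `summary` table (needs `or`, `pval` and an
#'   exposure label); points with FDR below `alpha` are highlighted.
#' @param alpha FDR highlight threshold (default 0.05).
#' @return A ggplot of log10 OR against -log10 p.
#' @export
plot_volcano <- function(summary, alpha = 0.05) {
  df <- mutate(summary,
               sig = if ("fdr" %in% names(summary)) .data$fdr < alpha else
                 .data$pval < alpha)
  ggplot2::ggplot(df, ggplot2::aes(x = log10(.data$or),
                                   y = -log10(.data$pval),
                                   colour = .data$sig)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "#b2182c"),
                                 guide = "none") +
    ggplot2::labs(x = "log10 odds ratio", y = "-log10 p (IVW)") +
    ggplot2::theme_minimal()
}
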