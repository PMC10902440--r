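#' Pathway over-representation analysis (hypergeometric)
#'
#' For each pathway with `S` members in a compound universe of size `B`,
#' tests whether the `k` hit compounds falling in it are more than
#' expected when drawing `|hits|` compounds at random: the one-sided
#' upper-tail hypergeometric probability `P(X >= k)` (including `k`, the
#' MetaboAnalyst ORA convention; `k = 0` gives p = 1). Holm and
#' Benjamini-Hochberg adjustments are applied across pathways.
#'
#' @param hits Character vector of hit compounds; must be a subset of the
#'   background.
#' @param library Pathway membership as a two-column data frame
#'   (`pathway`, `compound`) or a named list of compound vectors.
#' @param background Compound universe; defaults to the full library
#'   universe.
#' @return A tibble sorted by p-value with one row per pathway:
#'   `pathway`, `match_status` (`"k/S"`), `hits` (semicolon-collapsed
#'   matching compounds), `k`, `pathway_size`, `pval`, `holm_p`, `fdr`.
#' @export
#' @examples
#' lib <- tibble::tibble(pathway = rep(c("a", "b"), each = 3),
#'                       compound = c("c1", "c2", "c3", "c4", "c5", "c6"))
#' ora(c("c1", "c2"), lib)
ora <- function(hits, library, background = NULL) {
  if (is.list(library) && !is.data.frame(library)) {
    library <- purrr::map_dfr(names(library), function(p) {
      tibble(pathway = p, compound = library[[p]])
    })
  }
  stopifnot(all(c("pathway", "compound") %in% names(library)))
  library <- distinct(library, .data$pathway, .data$compound)
  background <- unique(background %||% library$compound)
  hits <- unique(hits)
  offenders <- setdiff(hits, background)
  if (length(offenders) > 0) {
    abort(paste0("ora: hit compound(s) not in background: ",
                 paste(offenders, collapse = ", ")))
  }
  stray <- setdiff(library$compound, background)
  if (length(stray) > 0) {
    abort(paste0("ora: pathway compound(s) not in background: ",
                 paste(head(stray, 5), collapse = ", ")))
  }
  B <- length(background)
  n_hits <- length(hits)
  rows <- library |>
    group_by(.data$pathway) |>
    summarise(pathway_size = dplyr::n(),
              k = sum(.data$compound %in% hits),
              hits = paste(intersect(hits, .data$compound), collapse = "; "),
              .groups = "drop") |>
    mutate(pval = phyper(.data$k - 1, .data$pathway_size,
                         B - .data$pathway_size, n_hits,
                         lower.tail = FALSE),
           match_status = sprintf("%d/%d", .data$k, .data$pathway_size),
           holm_p = p.adjust(.data$pval, method = "holm"),
           fdr = p.adjust(.data$pval, method = "BH")) |>
    arrange(.data$pval)
  select(rows, "pathway", "match_status", "hits", "k", "pathway_size",
         "pval", "holm_p", "fdr")
}
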