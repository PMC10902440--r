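#' Canonical summary-statistics columns
#'
#' Every mrpipe function consumes GWAS summary statistics as a tibble with
#' the canonical columns `snp`, `effect_allele`, `other_allele`, `eaf`,
#' `beta`, `se`, `pval`, `n` (plus optional `ncase`, `ncontrol` for binary
#' traits). `beta` is the per-allele effect: SD units for continuous traits,
#' log odds ratio for binary traits.
#'
#' @name sumstats-format
#' @keywords internal
NULL

# Row-level validity checks shared by read_sumstats() and harmonize().
# Returns a character vector of reasons ("" = valid).
sumstats_row_reason <- function(x) {
  reason <- rep("", nrow(x))
  bad <- function(cond, why) ifelse(reason == "" & cond, why, reason)
  ea <- toupper(x$effect_allele)
  oa <- toupper(x$other_allele)
  reason <- bad(is.na(x$snp) | x$snp == "", "missing snp id")
  reason <- bad(!(ea %in% BASES) | !(oa %in% BASES), "invalid allele")
  reason <- bad(ea == oa, "identical alleles")
  reason <- bad(!is.finite(x$beta), "nonfinite beta")
  reason <- bad(!is.finite(x$se) | x$se <= 0, "nonpositive SE")
  reason <- bad(!is.finite(x$eaf) | x$eaf < 0 | x$eaf > 1, "eaf outside [0,1]")
  reason <- bad(!is.finite(x$pval) | x$pval <= 0 | x$pval > 1,
                "pval outside (0,1]")
  reason <- bad(!is.finite(x$n) | x$n <= 0, "nonpositive n")
  reason
}

#' Read GWAS summary statistics from delimited text
#'
#' Reads a tab- or comma-delimited file with a header row, optionally
#' renaming source-specific column names to the canonical mrpipe schema,
#' and validates every row. Rows violating the schema invariants (for
#' example a non-positive standard error) are dropped with a logged reason
#' rather than failing the whole read.
#'
#' @param path Path to a delimited text file with a header.
#' @param dialect Optional named character vector mapping source column
#'   names to canonical ones, e.g. `c(rsids = "snp", alt = "effect_allele")`.
#'   Columns not mentioned are kept under their own names.
#' @param delim Field delimiter; guessed from the first line when `NULL`.
#'
#' @return A tibble of validated records in canonical column order. The
#'   number of skipped rows and their reasons are attached as the
#'   `"skipped"` attribute (a tibble with columns `row`, `snp`, `reason`)
#'   and retrievable with [skipped_records()].
#' @seealso [harmonize()], [write_sumstats()]
#' @export
#' @examples
#' p <- tempfile(fileext = ".tsv")
#' writeLines(c("snp\teffect_allele\tother_allele\teaf\tbeta\tse\tpval\tn",
#'              "rs1\tA\tG\t0.3\t0.1\t0.02\t1e-6\t18340"), p)
#' read_sumstats(p)
read_sumstats <- function(path, dialect = NULL, delim = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) abort(paste0("empty file: ", path))
  if (is.null(delim)) {
    delim <- if (lengths(regmatches(first, gregexpr("\t", first))) > 0) "\t" else ","
  }
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE)
  if (nrow(x) == 0L) abort(paste0("empty file: ", path))
  if (!is.null(dialect)) {
    found <- intersect(names(dialect), names(x))
    x <- rename(x, !!!setNames(found, dialect[found]))
  }
  missing <- setdiff(SUMSTATS_COLS, names(x))
  if (length(missing) > 0) {
    abort(paste0("missing mandatory column(s): ",
                 paste(missing, collapse = ", ")))
  }
  x <- mutate(x,
              snp = as.character(.data$snp),
              effect_allele = toupper(as.character(.data$effect_allele)),
              other_allele = toupper(as.character(.data$other_allele)),
              across(c("eaf", "beta", "se", "pval", "n"), as.numeric))
  reason <- sumstats_row_reason(x)
  skipped <- tibble(row = which(reason != ""),
                    snp = x$snp[reason != ""],
                    reason = reason[reason != ""])
  x <- x[reason == "", , drop = FALSE]
  if (nrow(skipped) > 0) {
    inform(sprintf("read_sumstats: skipped %d invalid row(s)", nrow(skipped)))
  }
  out <- select(x, all_of(SUMSTATS_COLS), any_of(c("ncase", "ncontrol")),
                everything())
  attr(out, "skipped") <- skipped
  out
}

#' @rdname read_sumstats
#' @param x A tibble returned by [read_sumstats()].
#' @export
skipped_records <- function(x) {
  attr(x, "skipped") %||% tibble(row = integer(), snp = character(),
                                 reason = character())
}

#' Write summary statistics or report tables as TSV
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(x)
}

is_palindromic <- function(ea, oa) unname(BASE_COMPLEMENT[ea] == oa)

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns outcome effects to the exposure's effect allele, the first-class
#' QC step of two-sample MR. SNPs are intersected on their identifier;
#' swapped-allele records have their outcome beta negated and frequency
#' complemented; strand flips (A/G recorded as T/C) are reconciled by
#' complementing alleles before comparison. Palindromic (A/T, C/G) variants
#' cannot be strand-resolved from alleles alone and are dropped when their
#' allele frequency is intermediate; outside that band the effect-allele
#' frequencies on the two sides decide the orientation. Irreconcilable
#' allele pairs and duplicates (keeping the smallest exposure p-value) are
#' dropped. Every exclusion carries a reason code.
#'
#' @param exposure,outcome Summary-statistic tibbles in the canonical
#'   format (see [read_sumstats()]).
#' @param palindrome_band Half-width of the "intermediate frequency" band
#'   around 0.5 within which palindromic SNPs are dropped. The default 0.08
#'   removes palindromic SNPs with effect-allele frequency in (0.42, 0.58).
#' @param proxy_table Optional two-column data frame (`snp`, `proxy`)
#'   substituting pre-computed LD proxies (r^2 > 0.8) for exposure SNPs
#'   absent from the outcome. The proxy's outcome record is relabelled
#'   with the exposure SNP id before intersection.
#'
#' @return A harmonized tibble of class `mr_harmonized` with columns `snp`,
#'   `beta_exp`, `se_exp`, `pval_exp`, `eaf`, `beta_out`, `se_out`,
#'   `pval_out`, `n_exp`, `n_out` (plus `ncase`/`ncontrol` when present on
#'   the outcome side). Per-SNP exclusions are attached as the
#'   `"exclusions"` attribute, retrievable with [exclusions()].
#' @export
#' @examples
#' exp <- tibble::tibble(snp = "rs1", effect_allele = "A", other_allele = "G",
#'   eaf = 0.3, beta = 0.1, se = 0.02, pval = 1e-6, n = 18340)
#' out <- tibble::tibble(snp = "rs1", effect_allele = "G", other_allele = "A",
#'   eaf = 0.7, beta = -0.05, se = 0.03, pval = 0.1, n = 347125)
#' harmonize(exp, out)$beta_out  # +0.05 after allele alignment
harmonize <- function(exposure, outcome, palindrome_band = 0.08,
                      proxy_table = NULL) {
  stopifnot(is.data.frame(exposure), is.data.frame(outcome))
  if (nrow(exposure) == 0 || nrow(outcome) == 0) {
    abort("harmonize: empty exposure or outcome set")
  }
  if (!(palindrome_band >= 0 && palindrome_band < 0.5)) {
    abort("palindrome_band must lie in [0, 0.5)")
  }
  if (!is.null(proxy_table)) {
    stopifnot(all(c("snp", "proxy") %in% names(proxy_table)))
    need <- setdiff(exposure$snp, outcome$snp)
    sub <- proxy_table[proxy_table$snp %in% need &
                         proxy_table$proxy %in% outcome$snp, , drop = FALSE]
    if (nrow(sub) > 0) {
      idx <- match(sub$proxy, outcome$snp)
      outcome$snp[idx] <- sub$snp
    }
  }

  excl <- tibble(snp = character(), reason = character())
  note <- function(snps, reason) {
    if (length(snps) > 0) {
      excl <<- bind_rows(excl, tibble(snp = snps, reason = reason))
    }
  }

  # duplicate resolution: smallest p wins on each side
  dedupe <- function(x, side) {
    x <- arrange(x, .data$snp, .data$pval)
    dup <- duplicated(x$snp)
    note(unique(x$snp[dup]), paste0("duplicate-", side))
    x[!dup, , drop = FALSE]
  }
  exposure <- dedupe(exposure, "exposure")
  outcome <- dedupe(outcome, "outcome")

  shared <- intersect(exposure$snp, outcome$snp)
  if (length(shared) == 0) abort("no overlapping SNPs")

  e <- exposure[match(shared, exposure$snp), , drop = FALSE]
  o <- outcome[match(shared, outcome$snp), , drop = FALSE]

  ea_e <- toupper(e$effect_allele); oa_e <- toupper(e$other_allele)
  ea_o <- toupper(o$effect_allele); oa_o <- toupper(o$other_allele)
  pal <- is_palindromic(ea_e, oa_e)
  ea_oc <- unname(BASE_COMPLEMENT[ea_o]); oa_oc <- unname(BASE_COMPLEMENT[oa_o])

  same <- ea_o == ea_e & oa_o == oa_e
  swap <- ea_o == oa_e & oa_o == ea_e
  flip_same <- !pal & ea_oc == ea_e & oa_oc == oa_e
  flip_swap <- !pal & ea_oc == oa_e & oa_oc == ea_e

  action <- rep(NA_character_, length(shared))
  action[same | flip_same] <- "keep"
  action[!(same | flip_same) & (swap | flip_swap)] <- "flip"

  # palindromic: alleles alone cannot orient; use allele frequency unless
  # it is intermediate
  intermediate <- pmin(e$eaf, 1 - e$eaf) > 0.5 - palindrome_band
  drop_pal <- pal & intermediate
  pal_flip <- pal & !intermediate & (e$eaf - 0.5) * (o$eaf - 0.5) < 0
  action[pal & !drop_pal] <- ifelse(pal_flip[pal & !drop_pal], "flip", "keep")
  action[drop_pal] <- "palindromic-intermediate"
  action[is.na(action)] <- "allele mismatch"

  note(shared[action == "palindromic-intermediate"], "palindromic-intermediate")
  note(shared[action == "allele mismatch"], "allele mismatch")

  keep <- action %in% c("keep", "flip")
  flip <- action == "flip"
  beta_out <- ifelse(flip, -o$beta, o$beta)
  eaf_out <- ifelse(flip, 1 - o$eaf, o$eaf)

  h <- tibble(
    snp = shared,
    effect_allele = ea_e,
    other_allele = oa_e,
    beta_exp = e$beta, se_exp = e$se, pval_exp = e$pval, eaf = e$eaf,
    beta_out = beta_out, se_out = o$se, pval_out = o$pval, eaf_out = eaf_out,
    n_exp = e$n, n_out = o$n
  )
  if ("ncase" %in% names(o)) h$ncase <- o$ncase
  if ("ncontrol" %in% names(o)) h$ncontrol <- o$ncontrol
  h <- h[keep, , drop = FALSE]
  as_harmonized(h, exclusions = excl)
}

#' Mark a tibble as a harmonized exposure/outcome set
#'
#' Users with already-aligned effect pairs (for example from an external
#' harmonization run) can enter the mrpipe estimator surface here.
#'
#' @param x A data frame with at least `snp`, `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out`.
#' @param exclusions Optional exclusion log tibble (`snp`, `reason`).
#' @return `x` as a tibble of class `mr_harmonized`.
#' @export
as_harmonized <- function(x, exclusions = NULL) {
  need <- c("snp", "beta_exp", "se_exp", "beta_out", "se_out")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    abort(paste0("as_harmonized: missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(x$snp)) abort("as_harmonized: duplicate snp ids")
  if (any(x$se_exp <= 0) || any(x$se_out <= 0)) {
    abort("as_harmonized: standard errors must be positive")
  }
  out <- as_tibble(x)
  class(out) <- unique(c("mr_harmonized", class(out)))
  attr(out, "exclusions") <- exclusions %||%
    tibble(snp = character(), reason = character())
  out
}

#' Exclusion log of a harmonized set
#'
#' @param x An `mr_harmonized` tibble (or any object carrying an
#'   `"exclusions"` attribute).
#' @return A tibble with columns `snp` and `reason`.
#' @export
exclusions <- function(x) {
  attr(x, "exclusions") %||% tibble(snp = character(), reason = character())
}
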