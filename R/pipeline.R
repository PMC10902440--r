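pipeline_defaults <- function() {
  list(
    exposures = NULL, outcome = NULL,
    exposure_dialect = NULL, outcome_dialect = NULL,
    simulate = NULL, family = NULL,
    palindrome_band = 0.08,
    iv = list(p_threshold = 1e-5, clump_r2 = 0.001, clump_kb = 10000,
              maf_min = 0.01, f_min = 10, r2_min = 0.005, k_min = 3),
    estimators = list(model = "auto", n_boot = 1000),
    presso = list(enabled = TRUE, n_sim = 1000, outlier_alpha = 0.05),
    steiger = list(enabled = TRUE),
    reverse = list(enabled = TRUE, p_threshold = 5e-8),
    fdr = list(alpha = 0.05, by_family = TRUE),
    mvmr = list(enabled = TRUE, alpha = 0.05),
    meta = NULL,
    confounders = list(annotations = NULL, traits = NULL,
                       p_threshold = 1e-5),
    ora = NULL,
    seed = NULL, out_dir = NULL)
}

#' Build a pipeline configuration
#'
#' Assembles the full analysis configuration with every threshold at its
#' standard default (instrument p < 1e-5, clumping r2 0.001 within
#' 10,000 kb, MAF 0.01, F >= 10, variance explained >= 0.5%, >= 3
#' instruments, test size 0.05, FDR 0.05). Values supplied here override
#' the defaults; nested lists are merged element-wise. A seed is
#' mandatory.
#'
#' @param ... Configuration entries overriding the defaults: `exposures`
#'   (named paths) + `outcome` (path) with optional dialect maps, or
#'   `simulate` (a list passed to [simulate_panel()]: `n_exposures`,
#'   `thetas`, `snps_per_exposure` plus [sim_config()] fields); `family`
#'   (named vector, exposure to family, for grouped FDR); the stage lists
#'   `iv`, `estimators`, `presso`, `steiger`, `reverse`, `fdr`, `mvmr`,
#'   `confounders`; `meta` (per-cohort table with `group`, `study`, `or`,
#'   `ci_low`, `ci_high` and optional `model`); `ora` (list with `hits`
#'   and `library`); `seed`; `out_dir`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  user <- list(...)
  cfg <- pipeline_defaults()
  for (nm in names(user)) {
    if (is.list(cfg[[nm]]) && is.list(user[[nm]]) &&
        !is.data.frame(user[[nm]]) && nm != "simulate") {
      cfg[[nm]] <- modifyList(cfg[[nm]], user[[nm]])
    } else {
      cfg[[nm]] <- user[[nm]]
    }
  }
  if (is.null(cfg$seed)) abort("pipeline_config: seed is mandatory")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file whose top-level keys mirror
#'   [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Remove instruments annotated to confounder traits
#'
#' Drops SNPs that a local annotation table (a stand-in for a PhenoScanner
#' lookup) links to any of the listed confounding traits below the given
#' p-value; the downstream IVW is then re-run on the reduced set to check
#' robustness to confounder-driven pleiotropy.
#'
#' @param h A harmonized set.
#' @param annotations Data frame with columns `snp`, `trait`, `p`.
#' @param traits Traits considered confounders; `NULL` means every trait
#'   in the table.
#' @param p_threshold Annotation significance threshold (default 1e-5).
#' @return The filtered harmonized set; removed SNPs (with their traits)
#'   are in the `"removed"` attribute.
#' @export
confounder_filter <- function(h, annotations, traits = NULL,
                              p_threshold = 1e-5) {
  check_harmonized(h, 1L, "confounder_filter")
  if (is.null(annotations) || nrow(annotations) == 0) {
    attr(h, "removed") <- tibble(snp = character(), trait = character())
    return(h)
  }
  stopifnot(all(c("snp", "trait", "p") %in% names(annotations)))
  ann <- filter(annotations, .data$p < p_threshold)
  if (!is.null(traits)) ann <- filter(ann, .data$trait %in% traits)
  removed <- filter(ann, .data$snp %in% h$snp) |>
    distinct(.data$snp, .data$trait)
  out <- h[!(h$snp %in% removed$snp), , drop = FALSE]
  attr(out, "exclusions") <- bind_rows(
    exclusions(h),
    tibble(snp = unique(removed$snp),
           reason = rep("confounder", length(unique(removed$snp)))))
  attr(out, "removed") <- removed
  out
}

load_pipeline_inputs <- function(cfg) {
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    panel_args <- sim_args[intersect(names(sim_args),
                                     c("n_exposures", "thetas",
                                       "snps_per_exposure",
                                       "exposure_names"))]
    sc_args <- sim_args[intersect(names(sim_args),
                                  setdiff(names(formals(sim_config)),
                                          c("seed", "n_snps", "theta")))]
    sc <- do.call(sim_config, c(sc_args,
                                list(seed = derive_seed(cfg$seed, "simulate"))))
    panel <- do.call(simulate_panel, c(panel_args, list(config = sc)))
    list(exposures = panel$exposures, outcome = panel$outcome,
         truth = panel$truth)
  } else {
    if (is.null(cfg$exposures) || is.null(cfg$outcome)) {
      abort("run_pipeline: supply either simulate or exposures + outcome")
    }
    exps <- lapply(cfg$exposures, read_sumstats, dialect = cfg$exposure_dialect)
    names(exps) <- names(cfg$exposures) %||%
      sub("\\.[^.]*$", "", basename(unlist(cfg$exposures)))
    list(exposures = exps,
         outcome = read_sumstats(cfg$outcome, dialect = cfg$outcome_dialect),
         truth = NULL)
  }
}

#' Run the full forward (and reverse) MR pipeline
#'
#' Executes, per exposure: instrument selection, harmonization against the
#' outcome, strength gates, the five estimators, heterogeneity and Egger
#' intercept tests, MR-PRESSO, the Steiger direction test and (optionally)
#' reverse MR; then BH-FDR across exposures (within exposure families when
#' given), confounder-SNP filtering with IVW re-estimation, multivariable
#' MR over the FDR-significant exposures, and optional replication
#' meta-analysis and pathway ORA. Fully deterministic under a fixed
#' configuration and seed, and invariant to the order exposures are listed
#' (per-exposure randomness is keyed by exposure name).
#'
#' @param config A [pipeline_config()].
#' @return An object of class `mr_report`: a named list of result tibbles
#'   (`estimates`, `sensitivity`, `steiger`, `reverse`, `summary`,
#'   `gates`, `filter_report`, `exclusions`, plus `confounder`, `mvmr`,
#'   `meta`, `ora` when those stages ran) and a `provenance` block. When
#'   `config$out_dir` is set every table is also written as TSV.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  inputs <- load_pipeline_inputs(cfg)
  exposures <- inputs$exposures
  outcome <- inputs$outcome
  nms <- names(exposures)

  per <- lapply(nms, function(nm) {
    stage <- "iv_selection"
    tryCatch({
      ex <- exposures[[nm]]
      iv <- select_instruments(ex, p_threshold = cfg$iv$p_threshold,
                               clump_r2 = cfg$iv$clump_r2,
                               clump_kb = cfg$iv$clump_kb,
                               maf_min = cfg$iv$maf_min)
      rep_tbl <- mutate(filter_report(iv), exposure = nm, .before = 1)
      if (nrow(iv) == 0) {
        return(list(name = nm, report = rep_tbl,
                    gates = mutate(strength_gates(iv), exposure = nm,
                                   .before = 1),
                    excl = tibble(exposure = character(), snp = character(),
                                  reason = character())))
      }
      stage <- "harmonize"
      h <- harmonize(iv, outcome, palindrome_band = cfg$palindrome_band)
      excl <- mutate(exclusions(h), exposure = nm, .before = 1)
      stage <- "strength_gates"
      iv_kept <- iv[iv$snp %in% h$snp, , drop = FALSE]
      gates <- mutate(strength_gates(iv_kept, f_min = cfg$iv$f_min,
                                     r2_min = cfg$iv$r2_min,
                                     k_min = cfg$iv$k_min),
                      exposure = nm, .before = 1)
      out <- list(name = nm, report = rep_tbl, gates = gates, excl = excl,
                  h = h)
      if (!gates$pass) return(out)

      stage <- "estimators"
      est <- mr_all(h, model = cfg$estimators$model,
                    n_boot = cfg$estimators$n_boot,
                    seed = derive_seed(cfg$seed, paste0("est:", nm)))
      het <- mr_heterogeneity(h)
      plt <- mr_pleiotropy_test(h)
      out$estimates <- mutate(est, exposure = nm, .before = 1)

      presso_p <- NA_real_
      if (isTRUE(cfg$presso$enabled) && nrow(h) >= 4) {
        stage <- "presso"
        pr <- mr_presso(h, n_sim = cfg$presso$n_sim,
                        outlier_alpha = cfg$presso$outlier_alpha,
                        seed = derive_seed(cfg$seed, paste0("presso:", nm)))
        presso_p <- pr$global_p
        out$presso <- pr
      }
      qe <- het[het$method == "MR Egger", ]
      qi <- het[het$method == "IVW", ]
      out$sensitivity <- tibble(
        exposure = nm, Q_egger = qe$Q, q_pval_egger = qe$q_pval,
        Q_ivw = qi$Q, q_pval_ivw = qi$q_pval,
        egger_intercept = plt$intercept, intercept_pval = plt$pval,
        presso_global_p = presso_p)

      if (isTRUE(cfg$steiger$enabled)) {
        stage <- "steiger"
        out$steiger <- mutate(mr_steiger(h), exposure = nm, .before = 1)
      }
      if (isTRUE(cfg$reverse$enabled)) {
        stage <- "reverse_mr"
        rev <- reverse_mr(outcome, exposures[[nm]],
                          p_threshold = cfg$reverse$p_threshold,
                          maf_min = cfg$iv$maf_min, n_boot = 0,
                          seed = derive_seed(cfg$seed, paste0("rev:", nm)))
        out$reverse <- if (rev$testable) {
          mutate(rev$estimates[rev$estimates$method == "IVW", ],
                 exposure = nm, testable = TRUE, .before = 1)
        } else {
          tibble(exposure = nm, testable = FALSE, method = "IVW",
                 n_snp = rev$k, b = NA_real_, se = NA_real_,
                 pval = NA_real_, or = NA_real_, or_lo = NA_real_,
                 or_hi = NA_real_, model = NA_character_,
                 direction = "reverse")
        }
      }
      out
    }, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed for exposure '%s': %s",
                    stage, nm, conditionMessage(e)))
    })
  })
  names(per) <- nms

  collect <- function(field) {
    tbls <- purrr::compact(purrr::map(per, field))
    if (length(tbls) == 0) return(NULL)
    out <- bind_rows(tbls)
    attr(out, "heterogeneity") <- NULL
    attr(out, "intercept") <- NULL
    attr(out, "exclusions") <- NULL
    out
  }
  report <- list(
    estimates = collect("estimates"),
    sensitivity = collect("sensitivity"),
    steiger = collect("steiger"),
    reverse = collect("reverse"),
    gates = collect("gates"),
    filter_report = collect("report"),
    exclusions = collect("excl"))

  # FDR summary across exposures (per family when supplied)
  if (!is.null(report$estimates)) {
    ivw <- filter(report$estimates, .data$method == "IVW")
    fam <- cfg$family %||% setNames(rep("all", nrow(ivw)), ivw$exposure)
    ivw$family <- unname(fam[ivw$exposure])
    ivw$family[is.na(ivw$family)] <- "all"
    grp <- if (isTRUE(cfg$fdr$by_family)) ivw$family else rep("all", nrow(ivw))
    ivw$fdr <- NA_real_
    for (g in unique(grp)) {
      i <- which(grp == g)
      ivw$fdr[i] <- bh_fdr(ivw$pval[i])
    }
    ivw$significant <- ivw$fdr < cfg$fdr$alpha
    report$summary <- arrange(ivw, .data$pval)
  }

  # confounder filtering + IVW re-run
  ann <- cfg$confounders$annotations
  if (!is.null(ann)) {
    if (is.character(ann)) ann <- readr::read_tsv(ann, show_col_types = FALSE)
    conf <- purrr::map_dfr(per, function(x) {
      if (is.null(x$h)) return(NULL)
      h2 <- confounder_filter(x$h, ann, traits = cfg$confounders$traits,
                              p_threshold = cfg$confounders$p_threshold)
      removed <- attr(h2, "removed")
      if (nrow(h2) < 2) return(NULL)
      mutate(mr_ivw(h2, model = cfg$estimators$model), exposure = x$name,
             n_removed = length(unique(removed$snp)),
             removed_snps = paste(unique(removed$snp), collapse = ";"),
             .before = 1)
    })
    report$confounder <- conf
  }

  # MVMR over FDR-significant exposures
  if (isTRUE(cfg$mvmr$enabled) && !is.null(report$summary)) {
    entrants <- report$summary$exposure[report$summary$significant]
    if (length(entrants) >= 2) {
      union_snps <- sort(unique(unlist(lapply(per[entrants],
                                              function(x) x$h$snp))))
      hs <- lapply(entrants, function(nm) {
        harmonize(exposures[[nm]][exposures[[nm]]$snp %in% union_snps, ,
                                  drop = FALSE],
                  outcome, palindrome_band = cfg$palindrome_band)
      })
      common <- Reduce(intersect, lapply(hs, function(h) h$snp))
      if (length(common) > length(entrants) + 2) {
        X <- vapply(hs, function(h) h$beta_exp[match(common, h$snp)],
                    numeric(length(common)))
        colnames(X) <- entrants
        h1 <- hs[[1]][match(common, hs[[1]]$snp), ]
        report$mvmr <- mvmr_ivw(X, h1$beta_out, h1$se_out, snp = common)
        pr <- mvmr_presso(X, h1$beta_out, h1$se_out, snp = common,
                          n_sim = cfg$presso$n_sim,
                          seed = derive_seed(cfg$seed, "mvmr_presso"))
        report$mvmr_presso <- glance(pr)
      }
    }
  }

  if (!is.null(cfg$meta)) {
    meta_tbl <- cfg$meta
    if (is.character(meta_tbl)) {
      meta_tbl <- readr::read_tsv(meta_tbl, show_col_types = FALSE)
    }
    report$meta <- purrr::map_dfr(split(meta_tbl, meta_tbl$group),
                                  function(g) {
      model <- if ("model" %in% names(g)) g$model[1] else "fixed"
      mutate(mr_meta(g, model = model), group = g$group[1], .before = 1)
    })
  }

  if (!is.null(cfg$ora)) {
    report$ora <- ora(cfg$ora$hits, cfg$ora$library,
                      background = cfg$ora$background)
  }

  cfg_for_hash <- unclass(cfg)
  cfg_for_hash$out_dir <- NULL
  report$provenance <- list(
    package = "mrpipe",
    version = as.character(utils::packageVersion("mrpipe")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    config_hash = rlang::hash(cfg_for_hash))
  if (!is.null(inputs$truth)) report$truth <- inputs$truth
  class(report) <- "mr_report"

  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' Write every table of an analysis report as TSV
#'
#' @param report An `mr_report`.
#' @param out_dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report)) {
    x <- report[[nm]]
    if (is.data.frame(x)) {
      readr::write_tsv(x, file.path(out_dir, paste0(nm, ".tsv")),
                       progress = FALSE)
    }
  }
  jsonlite::write_json(report$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.mr_report <- function(x, ...) {
  cat("MR analysis report\n")
  if (!is.null(x$summary)) {
    cat(sprintf("  %d exposure(s) analysed, %d FDR-significant\n",
                nrow(x$summary), sum(x$summary$significant)))
  }
  cat("  tables:", paste(names(Filter(is.data.frame, x)), collapse = ", "),
      "\n")
  invisible(x)
}
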