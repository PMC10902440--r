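#' Simulation configuration for a synthetic exposure/outcome GWAS pair
#'
#' Bundles the generating parameters for [simulate_pair()]. The defaults
#' emulate the statistical structure of the study conditions this package
#' targets: a microbiome-scale quantitative exposure GWAS (n = 18,340,
#' MAF above 0.05, hundreds of weak instruments at p < 1e-5 jointly
#' explaining about 1.5% of exposure variance, the level implied by a
#' median instrument F-statistic near 21 with ~13 instruments) against a
#' biobank-scale binary outcome on the log-odds scale (n = 347,125 with
#' 8,075 cases, so a case fraction near 2.3%).
#'
#' @param n_snps Number of independent candidate instruments.
#' @param n_exp,n_out Exposure and outcome GWAS sample sizes.
#' @param maf_range Interval within (0, 0.5] from which minor allele
#'   frequencies are drawn uniformly.
#' @param target_r2 Total exposure variance jointly explained by the
#'   instruments (per-SNP effects are rescaled to hit it exactly).
#' @param theta True causal effect, log-OR per SD of exposure.
#' @param pleio_frac Fraction of SNPs with direct (horizontal pleiotropic)
#'   outcome effects.
#' @param pleio_mean,pleio_sd Mean and SD of those direct effects; a
#'   non-zero mean induces directional pleiotropy.
#' @param rho_inside Correlation between instrument strength and direct
#'   effects among pleiotropic SNPs; non-zero values violate the InSIDE
#'   assumption under which MR-Egger is consistent.
#' @param case_frac Outcome case fraction (binary trait).
#' @param n_ld_clusters Optional number of synthetic LD clusters; when set,
#'   SNPs are tagged with a `ld_cluster` column marking groups treated as
#'   mutually correlated by [select_instruments()].
#' @param seed Integer seed; identical seeds give byte-identical output.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 200, n_exp = 18340, n_out = 347125,
                       maf_range = c(0.05, 0.5), target_r2 = 0.015,
                       theta = 0, pleio_frac = 0, pleio_mean = 0,
                       pleio_sd = 0, rho_inside = 0,
                       case_frac = 8075 / 347125,
                       n_ld_clusters = NULL, seed = 1L) {
  stopifnot(n_snps >= 1, n_exp > 1, n_out > 1,
            length(maf_range) == 2, case_frac > 0, case_frac < 1,
            pleio_frac >= 0, pleio_frac <= 1,
            target_r2 > 0, target_r2 < 1,
            abs(rho_inside) <= 1)
  if (maf_range[2] <= 0 || diff(maf_range) < 0 ||
      (maf_range[1] == 0 && maf_range[2] == 0)) {
    abort("degenerate maf_range")
  }
  if (maf_range[1] <= 0) abort("maf_range must lie within (0, 0.5]")
  structure(list(n_snps = n_snps, n_exp = n_exp, n_out = n_out,
                 maf_range = maf_range, target_r2 = target_r2,
                 theta = theta, pleio_frac = pleio_frac,
                 pleio_mean = pleio_mean, pleio_sd = pleio_sd,
                 rho_inside = rho_inside, case_frac = case_frac,
                 n_ld_clusters = n_ld_clusters, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate an exposure/outcome summary-statistics pair with known truth
#'
#' Generates LD-free per-SNP association summaries under a linear
#' structural model: per-allele exposure effects `gamma` are drawn and
#' rescaled so that the variance explained, `sum(2 maf (1-maf) gamma^2)`,
#' equals `target_r2` exactly; observed exposure betas add sampling noise
#' with `se_exp = 1/sqrt(2 maf (1-maf) n_exp)`; outcome betas are
#' `theta * gamma + alpha` plus noise with the binary-trait (logistic
#' approximation) standard error
#' `1/sqrt(2 maf (1-maf) n_out case_frac (1-case_frac))`, where `alpha`
#' are the direct pleiotropic effects.
#'
#' @param config A [sim_config()].
#' @return A list with elements `exposure` and `outcome` (canonical
#'   summary-statistic tibbles sharing SNP ids and alleles) and `truth`
#'   (a list with `theta` and a per-SNP tibble of `gamma`, `alpha` and
#'   variance explained `r2`).
#' @export
#' @examples
#' sim <- simulate_pair(sim_config(n_snps = 50, seed = 7))
#' sum(sim$truth$snps$r2)  # equals target_r2
simulate_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    k <- config$n_snps
    maf <- runif(k, config$maf_range[1], config$maf_range[2])
    het <- 2 * maf * (1 - maf)

    gamma <- rnorm(k)
    gamma <- gamma * sqrt(config$target_r2 / sum(het * gamma^2))

    alpha <- numeric(k)
    is_pleio <- runif(k) < config$pleio_frac
    npl <- sum(is_pleio)
    if (npl > 0) {
      z <- rnorm(npl)
      if (config$rho_inside != 0 && npl > 1) {
        g <- gamma[is_pleio]
        gs <- (g - mean(g)) / max(sd(g), .Machine$double.eps)
        z <- config$rho_inside * gs + sqrt(1 - config$rho_inside^2) * z
      }
      # direct effects are oriented by the exposure-increasing allele, so
      # a non-zero mean is directional after the conventional MR
      # re-orientation of instruments
      alpha[is_pleio] <- sign(gamma[is_pleio]) *
        (config$pleio_mean + config$pleio_sd * z)
    }

    se_exp <- 1 / sqrt(het * config$n_exp)
    se_out <- 1 / sqrt(het * config$n_out *
                         config$case_frac * (1 - config$case_frac))
    beta_exp <- rnorm(k, gamma, se_exp)
    beta_out <- rnorm(k, config$theta * gamma + alpha, se_out)

    pair_idx <- sample.int(nrow(NONPAL_PAIRS), k, replace = TRUE)
    ea <- NONPAL_PAIRS[pair_idx, 1]
    oa <- NONPAL_PAIRS[pair_idx, 2]
    snp <- sprintf("rs%06d", seq_len(k))

    exposure <- tibble(
      snp = snp, effect_allele = ea, other_allele = oa, eaf = maf,
      beta = beta_exp, se = se_exp,
      pval = pmax(2 * pnorm(-abs(beta_exp / se_exp)), 1e-300),
      n = config$n_exp)
    if (!is.null(config$n_ld_clusters)) {
      exposure$ld_cluster <- sample.int(config$n_ld_clusters, k,
                                        replace = TRUE)
    }
    outcome <- tibble(
      snp = snp, effect_allele = ea, other_allele = oa, eaf = maf,
      beta = beta_out, se = se_out,
      pval = pmax(2 * pnorm(-abs(beta_out / se_out)), 1e-300),
      n = config$n_out,
      ncase = round(config$case_frac * config$n_out),
      ncontrol = round((1 - config$case_frac) * config$n_out))

    truth <- list(theta = config$theta,
                  snps = tibble(snp = snp, maf = maf, gamma = gamma,
                                alpha = alpha, r2 = het * gamma^2))
    list(exposure = exposure, outcome = outcome, truth = truth)
  })
}

#' Simulate a multi-exposure panel sharing one SNP set
#'
#' Builds `n_exposures` exposures over a common SNP panel, each with its
#' own block of causal instruments (non-zero `gamma` only on its block) but
#' with observed betas reported at every panel SNP, so multivariable MR has
#' complete exposure-beta matrices. The single binary outcome aggregates
#' all exposures' causal contributions plus optional pleiotropy.
#'
#' @param n_exposures Number of exposures.
#' @param thetas True causal effects, recycled to `n_exposures`.
#' @param snps_per_exposure Instruments per exposure block.
#' @param config A [sim_config()] providing shared parameters (sample
#'   sizes, MAF range, per-exposure `target_r2`, pleiotropy, seed);
#'   its `n_snps` and `theta` are ignored.
#' @param exposure_names Optional names (default `exp01`, `exp02`, ...).
#'
#' @return A list with `exposures` (named list of summary tibbles over the
#'   full panel), `outcome` (one summary tibble) and `truth` (thetas and
#'   per-SNP effect matrix).
#' @export
simulate_panel <- function(n_exposures, thetas = 0, snps_per_exposure = 15,
                           config = sim_config(), exposure_names = NULL) {
  stopifnot(n_exposures >= 1, snps_per_exposure >= 1)
  thetas <- rep_len(thetas, n_exposures)
  nm <- exposure_names %||% sprintf("exp%02d", seq_len(n_exposures))
  with_seed(config$seed, {
    k <- n_exposures * snps_per_exposure
    maf <- runif(k, config$maf_range[1], config$maf_range[2])
    het <- 2 * maf * (1 - maf)
    snp <- sprintf("rs%06d", seq_len(k))
    pair_idx <- sample.int(nrow(NONPAL_PAIRS), k, replace = TRUE)
    ea <- NONPAL_PAIRS[pair_idx, 1]
    oa <- NONPAL_PAIRS[pair_idx, 2]

    gamma <- matrix(0, k, n_exposures, dimnames = list(snp, nm))
    for (e in seq_len(n_exposures)) {
      blk <- ((e - 1) * snps_per_exposure + 1):(e * snps_per_exposure)
      g <- rnorm(snps_per_exposure)
      g <- g * sqrt(config$target_r2 / sum(het[blk] * g^2))
      gamma[blk, e] <- g
    }

    alpha <- numeric(k)
    is_pleio <- runif(k) < config$pleio_frac
    if (any(is_pleio)) {
      g_sign <- sign(rowSums(gamma)[is_pleio])
      g_sign[g_sign == 0] <- 1
      alpha[is_pleio] <- g_sign * rnorm(sum(is_pleio), config$pleio_mean,
                                        config$pleio_sd)
    }

    se_exp <- 1 / sqrt(het * config$n_exp)
    se_out <- 1 / sqrt(het * config$n_out *
                         config$case_frac * (1 - config$case_frac))
    exposures <- lapply(seq_len(n_exposures), function(e) {
      b <- rnorm(k, gamma[, e], se_exp)
      tibble(snp = snp, effect_allele = ea, other_allele = oa, eaf = maf,
             beta = b, se = se_exp,
             pval = pmax(2 * pnorm(-abs(b / se_exp)), 1e-300),
             n = config$n_exp)
    })
    names(exposures) <- nm
    mu_out <- drop(gamma %*% thetas) + alpha
    b_out <- rnorm(k, mu_out, se_out)
    outcome <- tibble(snp = snp, effect_allele = ea, other_allele = oa,
                      eaf = maf, beta = b_out, se = se_out,
                      pval = pmax(2 * pnorm(-abs(b_out / se_out)), 1e-300),
                      n = config$n_out,
                      ncase = round(config$case_frac * config$n_out),
                      ncontrol = round((1 - config$case_frac) * config$n_out))
    list(exposures = exposures, outcome = outcome,
         truth = list(thetas = setNames(thetas, nm), gamma = gamma,
                      alpha = alpha, maf = maf))
  })
}

#' Simulate LD-score tables with planted heritability and genetic correlation
#'
#' Draws per-SNP z-scores for one or two traits under the LD-score
#' regression model: `E[z1^2] = 1 + n1 h2_1 l / M` and
#' `E[z1 z2] = sqrt(n1 n2) rg sqrt(h2_1 h2_2) l / M`, where `l` is the
#' SNP's LD score and `M` the number of SNPs the heritability is spread
#' over. LD scores are drawn as `1 + Gamma(shape 2, scale 60)`, giving a
#' realistic long-tailed distribution with mean near 120.
#'
#' @param n_snps Number of regression SNPs to emit.
#' @param M Total SNPs represented (>= `n_snps`).
#' @param h2_1,h2_2 SNP heritabilities in `[0, 1]`; `h2_2 = NULL` emits a
#'   single trait.
#' @param rg Genetic correlation in `[-1, 1]`.
#' @param n1,n2 GWAS sample sizes.
#' @param seed Integer seed.
#' @return A tibble with columns `snp`, `ld`, `z1` (and `z2`).
#' @export
simulate_ld_scores <- function(n_snps, M = n_snps, h2_1, h2_2 = NULL,
                               rg = 0, n1, n2 = NULL, seed = 1L) {
  if (abs(rg) > 1) abort("rg must lie in [-1, 1]")
  stopifnot(h2_1 >= 0, h2_1 <= 1, M >= n_snps)
  if (!is.null(h2_2)) stopifnot(h2_2 >= 0, h2_2 <= 1, !is.null(n2))
  with_seed(seed, {
    ld <- 1 + rgamma(n_snps, shape = 2, scale = 60)
    v1 <- 1 + n1 * h2_1 * ld / M
    z1 <- rnorm(n_snps, 0, sqrt(v1))
    out <- tibble(snp = sprintf("rs%06d", seq_len(n_snps)), ld = ld, z1 = z1)
    if (!is.null(h2_2)) {
      v2 <- 1 + n2 * h2_2 * ld / M
      cv <- sqrt(n1 * n2) * rg * sqrt(h2_1 * h2_2) * ld / M
      # conditional normal draw gives the exact joint covariance
      mu2 <- cv / v1 * z1
      s2 <- pmax(v2 - cv^2 / v1, 0)
      out$z2 <- rnorm(n_snps, mu2, sqrt(s2))
    }
    out
  })
}

#' Simulate a pathway membership library
#'
#' Samples pathways without replacement from a synthetic compound
#' universe, for exercising [ora()] without any external database.
#'
#' @param n_compounds Size of the compound universe.
#' @param n_pathways Number of pathways.
#' @param size_range Integer range of pathway sizes (inclusive).
#' @param seed Integer seed.
#' @return A two-column tibble (`pathway`, `compound`).
#' @export
simulate_pathway_library <- function(n_compounds, n_pathways,
                                     size_range = c(3, 30), seed = 1L) {
  stopifnot(n_compounds >= max(size_range), n_pathways >= 1,
            size_range[1] >= 1, size_range[1] <= size_range[2])
  with_seed(seed, {
    universe <- sprintf("cmpd%04d", seq_len(n_compounds))
    purrr::map_dfr(seq_len(n_pathways), function(i) {
      s <- if (size_range[1] == size_range[2]) size_range[1] else
        sample(size_range[1]:size_range[2], 1)
      tibble(pathway = sprintf("pathway%03d", i),
             compound = sample(universe, s))
    })
  })
}
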