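# shared fixture builders

make_sumstats <- function(snp, ea, oa, eaf, beta, se,
                          pval = 2 * pnorm(-abs(beta / se)), n = 10000) {
  tibble::tibble(snp = snp, effect_allele = ea, other_allele = oa,
                 eaf = eaf, beta = beta, se = se, pval = pval, n = n)
}

make_h <- function(bx, by, byse, bxse = rep(0.01, length(bx)),
                   eaf = rep(0.3, length(bx)),
                   n_exp = 18340, n_out = 347125) {
  as_harmonized(tibble::tibble(
    snp = sprintf("rs%03d", seq_along(bx)),
    beta_exp = bx, se_exp = bxse, pval_exp = 2 * pnorm(-abs(bx / bxse)),
    eaf = eaf, beta_out = by, se_out = byse,
    pval_out = 2 * pnorm(-abs(by / byse)),
    n_exp = n_exp, n_out = n_out))
}

# random harmonized fixture with heterogeneous weights
random_h <- function(k, seed) {
  set.seed(seed)
  make_h(bx = rnorm(k, 0.1, 0.03),
         by = rnorm(k, 0.05, 0.04),
         byse = runif(k, 0.01, 0.08),
         bxse = runif(k, 0.005, 0.02))
}

# strong-instrument validation panel for estimator recovery checks
recovery_config <- function(seed, n_snps = 100, theta = 0.5, ...) {
  sim_config(n_snps = n_snps, n_exp = 5e5, target_r2 = 0.05,
             theta = theta, seed = seed, ...)
}

sim_h <- function(seed, ...) {
  sim <- simulate_pair(recovery_config(seed, ...))
  harmonize(sim$exposure, sim$outcome)
}
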