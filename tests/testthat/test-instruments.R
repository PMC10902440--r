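test_that("f_statistic matches the closed form", {
  expect_equal(f_statistic(0.02, 1000, 1), (0.02 / 0.98) * 998)
  expect_equal(f_statistic(0.02, 1000, 1), 20.367, tolerance = 1e-4)
  expect_equal(f_statistic(0.5, 103, 2), 50)
  expect_equal(f_statistic(0, 100, 3), 0)
  expect_error(f_statistic(0.1, 4, 3), "n > k")
  # randomized agreement with an independent transcription
  set.seed(1)
  for (i in 1:50) {
    r2 <- runif(1, 0, 0.5); n <- sample(100:50000, 1); k <- sample(1:30, 1)
    expect_equal(f_statistic(r2, n, k), r2 / (1 - r2) * (n - k - 1) / k)
  }
})

test_that("variance_explained: null effect, eaf symmetry, boundary", {
  expect_equal(variance_explained(0, 0.02, 0.3, 10000), 0)
  expect_equal(variance_explained(0.1, 0.02, 0.3, 10000),
               variance_explained(0.1, 0.02, 0.7, 10000))
  expect_warning(r2 <- variance_explained(0.1, 0.02, 1, 10000),
                 "monomorphic")
  expect_equal(r2, 0)
})

test_that("variance_explained recovers planted per-SNP variance", {
  # one SNP explaining 0.4% at n = 20,000, estimated over replicates
  reps <- 200
  n <- 20000
  set.seed(7)
  est <- vapply(seq_len(reps), function(i) {
    maf <- 0.3
    het <- 2 * maf * (1 - maf)
    gamma <- sqrt(0.004 / het)
    se <- 1 / sqrt(het * n)
    b <- rnorm(1, gamma, se)
    variance_explained(b, se, maf, n)
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.004) / 0.004, 0.2)
})

test_that("selection cascade filters on p, MAF and LD clusters", {
  stats <- make_sumstats(paste0("rs", 1:5), rep("A", 5), rep("G", 5),
                         eaf = c(0.3, 0.2, 0.005, 0.4, 0.25),
                         beta = rep(0.1, 5), se = rep(0.02, 5),
                         pval = c(1e-8, 1e-7, 1e-9, 1e-6, 2e-6))
  iv <- select_instruments(stats, ld_clusters = c("a", "a", "b", "c", "d"))
  # rs2 loses the cluster to rs1; rs3 fails MAF
  expect_setequal(iv$snp, c("rs1", "rs4", "rs5"))
  drops <- attr(iv, "drops")
  expect_equal(drops$reason[drops$snp == "rs2"], "clumped")
  expect_equal(drops$reason[drops$snp == "rs3"], "MAF<0.01")
  rep_tbl <- filter_report(iv)
  expect_equal(rep_tbl$n_before[-1], rep_tbl$n_after[-nrow(rep_tbl)])
})

test_that("selection agrees with a brute-force reimplementation", {
  set.seed(42)
  k <- 100
  stats <- make_sumstats(sprintf("rs%03d", 1:k), rep("A", k), rep("G", k),
                         eaf = runif(k, 0.001, 0.5),
                         beta = rnorm(k, 0, 0.05), se = runif(k, 0.01, 0.03),
                         pval = 10^runif(k, -9, -2))
  clusters <- sample(paste0("cl", 1:40), k, replace = TRUE)
  iv <- select_instruments(stats, p_threshold = 1e-5, maf_min = 0.01,
                           ld_clusters = clusters)
  # independent naive filter
  keep <- stats$pval < 1e-5 & pmin(stats$eaf, 1 - stats$eaf) >= 0.01
  naive <- stats[keep, ]
  ncl <- clusters[keep]
  winners <- unlist(lapply(split(seq_len(nrow(naive)), ncl), function(i) {
    naive$snp[i][which.min(naive$pval[i])]
  }))
  expect_setequal(iv$snp, winners)
})

test_that("pairwise LD tables clump through connected components", {
  stats <- make_sumstats(paste0("rs", 1:4), rep("A", 4), rep("G", 4),
                         eaf = 0.3, beta = 0.1, se = 0.02,
                         pval = c(1e-8, 1e-7, 1e-6, 1e-9))
  ld <- data.frame(snp_a = c("rs1", "rs2"), snp_b = c("rs2", "rs3"),
                   r2 = c(0.9, 0.5))
  iv <- select_instruments(stats, ld_clusters = ld)
  # rs1-rs2-rs3 chain collapses to rs1 (smallest p)
  expect_setequal(iv$snp, c("rs1", "rs4"))
})

test_that("strength gates evaluate and report all three conditions", {
  iv2 <- make_sumstats(paste0("rs", 1:2), rep("A", 2), rep("G", 2),
                       eaf = 0.3, beta = 0.08, se = 0.012, n = 18340)
  g <- strength_gates(iv2)
  expect_false(g$pass)
  expect_match(g$reasons, "fewer than 3 SNPs")

  iv3 <- make_sumstats(paste0("rs", 1:3), rep("A", 3), rep("G", 3),
                       eaf = 0.3, beta = 0.02, se = 0.012, n = 18340)
  g3 <- strength_gates(iv3)
  expect_false(g3$pass)
  expect_match(g3$reasons, "variance explained < 0.5%")

  iv10 <- make_sumstats(sprintf("rs%02d", 1:10), rep("A", 10), rep("G", 10),
                        eaf = 0.3, beta = 0.1, se = 0.011, n = 18340)
  g10 <- strength_gates(iv10)
  expect_true(g10$pass)
  expect_equal(g10$reasons, "")
})

test_that("power formula: size at the null, monotonicity, simulation oracle", {
  expect_equal(mr_power(40000, 0.1, 0.01, or_alt = 1), 0.05)
  expect_equal(mr_power(40000, 0.1, 0, or_alt = 1.5), 0.05)
  p <- mr_power(c(1e4, 2e4, 4e4), 0.1, 0.01, 1.5)
  expect_true(all(diff(p) > 0))
  expect_gt(mr_power(4e4, 0.1, 0.02, 1.5), mr_power(4e4, 0.1, 0.01, 1.5))
  expect_gt(mr_power(4e4, 0.1, 0.01, 2.0), mr_power(4e4, 0.1, 0.01, 1.5))

  # Monte-Carlo oracle at (n=40k, case 10%, r2=1%, OR=1.5)
  reps <- 400
  rej <- vapply(seq_len(reps), function(i) {
    sim <- simulate_pair(sim_config(
      n_snps = 50, n_exp = 2e6, n_out = 4e4, case_frac = 0.1,
      target_r2 = 0.01, theta = log(1.5), seed = 5000 + i))
    h <- harmonize(sim$exposure, sim$outcome)
    mr_ivw(h, model = "fixed")$pval < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - mr_power(4e4, 0.1, 0.01, 1.5)), 0.05)
})
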