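write_fixture <- function(lines, ext = ".tsv") {
  p <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, p)
  p
}

test_that("read_sumstats parses well-formed tables and skips invalid rows", {
  p <- write_fixture(c(
    "snp\teffect_allele\tother_allele\teaf\tbeta\tse\tpval\tn",
    "rs1\tA\tG\t0.3\t0.10\t0.02\t1e-6\t18340",
    "rs2\tC\tT\t0.1\t-0.05\t0.03\t0.04\t18340",
    "rs3\tG\tA\t0.5\t0.02\t0.01\t0.5\t18340"))
  x <- read_sumstats(p)
  expect_equal(nrow(x), 3)
  expect_equal(nrow(skipped_records(x)), 0)
  expect_named(x, c("snp", "effect_allele", "other_allele", "eaf",
                    "beta", "se", "pval", "n"))

  p2 <- write_fixture(c(
    "snp\teffect_allele\tother_allele\teaf\tbeta\tse\tpval\tn",
    "rs1\tA\tG\t0.3\t0.10\t0\t1e-6\t18340",
    "rs2\tC\tT\t0.1\t-0.05\t0.03\t0.04\t18340"))
  expect_message(x2 <- read_sumstats(p2), "skipped 1")
  expect_equal(x2$snp, "rs2")
  expect_equal(skipped_records(x2)$reason, "nonpositive SE")
})

test_that("a dialect remap reproduces the canonical-dialect read", {
  rows <- data.frame(
    snp = c("rs1", "rs2", "rs3", "rs4", "rs5"),
    ea = c("A", "C", "G", "T", "A"), oa = c("G", "T", "A", "C", "C"),
    eaf = c(0.1, 0.2, 0.3, 0.4, 0.25),
    beta = c(0.1, -0.2, 0.05, 0.3, -0.15),
    se = c(0.02, 0.05, 0.01, 0.07, 0.03),
    pval = c(1e-7, 6e-5, 6e-7, 2e-5, 6e-7), n = 18340)
  canon <- write_fixture(c(
    "snp\teffect_allele\tother_allele\teaf\tbeta\tse\tpval\tn",
    sprintf("%s\t%s\t%s\t%g\t%g\t%g\t%g\t%d", rows$snp, rows$ea, rows$oa,
            rows$eaf, rows$beta, rows$se, rows$pval, rows$n)))
  finngen <- write_fixture(c(
    "rsids\talt\tref\taf_alt\tbeta\tsebeta\tpval\tn",
    sprintf("%s\t%s\t%s\t%g\t%g\t%g\t%g\t%d", rows$snp, rows$ea, rows$oa,
            rows$eaf, rows$beta, rows$se, rows$pval, rows$n)))
  a <- read_sumstats(canon)
  b <- read_sumstats(finngen, dialect = c(rsids = "snp",
                                          alt = "effect_allele",
                                          ref = "other_allele",
                                          af_alt = "eaf", sebeta = "se"))
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("missing mandatory columns and empty files are hard errors", {
  p <- write_fixture(c("snp\teffect_allele\tother_allele\teaf\tbeta\tse\tpval",
                       "rs1\tA\tG\t0.3\t0.1\t0.02\t1e-6"))
  expect_error(read_sumstats(p), "n")
  p2 <- write_fixture("snp\teffect_allele\tother_allele\teaf\tbeta\tse\tpval\tn")
  expect_error(read_sumstats(p2), "empty")
})

test_that("harmonize flips swapped alleles and complements frequency", {
  exp <- make_sumstats("rs1", "A", "G", 0.3, 0.10, 0.02)
  out <- make_sumstats("rs1", "G", "A", 0.7, -0.05, 0.03)
  h <- harmonize(exp, out)
  expect_equal(h$beta_out, 0.05)
  expect_equal(h$eaf_out, 0.3)
  expect_equal(h$beta_exp, 0.10)
})

test_that("palindromic SNPs at intermediate frequency are dropped", {
  exp <- make_sumstats(c("rs1", "rs2"), c("A", "A"), c("T", "G"),
                       c(0.50, 0.3), c(0.1, 0.1), c(0.02, 0.02))
  out <- make_sumstats(c("rs1", "rs2"), c("A", "A"), c("T", "G"),
                       c(0.50, 0.3), c(0.05, 0.05), c(0.03, 0.03))
  h <- harmonize(exp, out, palindrome_band = 0.08)
  expect_equal(h$snp, "rs2")
  log <- exclusions(h)
  expect_equal(log$snp, "rs1")
  expect_equal(log$reason, "palindromic-intermediate")
})

test_that("allele reconciliation matches the hand-built truth table", {
  # exposure fixed at A/G, eaf 0.2; outcome runs over all 12 ordered pairs
  pairs <- subset(expand.grid(ea = c("A", "C", "G", "T"),
                              oa = c("A", "C", "G", "T"),
                              stringsAsFactors = FALSE), ea != oa)
  # truth: A/G direct keep; G/A swap-flip; T/C strand-flip keep;
  # C/T strand+swap flip; everything else mismatch
  expected <- function(ea, oa) {
    if (ea == "A" && oa == "G") "keep"
    else if (ea == "G" && oa == "A") "flip"
    else if (ea == "T" && oa == "C") "keep"
    else if (ea == "C" && oa == "T") "flip"
    else "mismatch"
  }
  for (i in seq_len(nrow(pairs))) {
    exp <- make_sumstats("rs1", "A", "G", 0.2, 0.10, 0.02)
    out <- make_sumstats("rs1", pairs$ea[i], pairs$oa[i], 0.2, 0.05, 0.03)
    want <- expected(pairs$ea[i], pairs$oa[i])
    if (want == "mismatch") {
      expect_error(h <- harmonize(exp, out), NA)
      expect_equal(nrow(h), 0, info = paste(pairs$ea[i], pairs$oa[i]))
      expect_equal(exclusions(h)$reason, "allele mismatch")
    } else {
      h <- harmonize(exp, out)
      expect_equal(h$beta_out, if (want == "flip") -0.05 else 0.05,
                   info = paste(pairs$ea[i], pairs$oa[i]))
    }
  }
})

test_that("duplicates resolve to the smallest exposure p-value", {
  exp <- make_sumstats(c("rs1", "rs1"), c("A", "A"), c("G", "G"),
                       c(0.3, 0.3), c(0.10, 0.20), c(0.02, 0.02),
                       pval = c(1e-6, 1e-9))
  out <- make_sumstats("rs1", "A", "G", 0.3, 0.05, 0.03)
  h <- harmonize(exp, out)
  expect_equal(h$beta_exp, 0.20)
  expect_true("duplicate-exposure" %in% exclusions(h)$reason)
})

test_that("empty SNP intersection is a hard error", {
  exp <- make_sumstats("rs1", "A", "G", 0.3, 0.1, 0.02)
  out <- make_sumstats("rs2", "A", "G", 0.3, 0.1, 0.02)
  expect_error(harmonize(exp, out), "no overlapping SNPs")
})

test_that("proxy substitution recovers exposure SNPs missing in the outcome", {
  exp <- make_sumstats("rs1", "A", "G", 0.3, 0.1, 0.02)
  out <- make_sumstats("rs9", "A", "G", 0.3, 0.05, 0.03)
  expect_error(harmonize(exp, out), "no overlapping SNPs")
  h <- harmonize(exp, out, proxy_table = data.frame(snp = "rs1",
                                                    proxy = "rs9"))
  expect_equal(h$snp, "rs1")
  expect_equal(h$beta_out, 0.05)
})

test_that("harmonize is idempotent and an involution under allele swap", {
  for (seed in 1:5) {
    sim <- simulate_pair(sim_config(n_snps = 40, theta = 0.3, seed = seed))
    h1 <- harmonize(sim$exposure, sim$outcome)

    # reconstruct summary tables from the harmonized set and re-harmonize
    exp2 <- make_sumstats(h1$snp, h1$effect_allele, h1$other_allele,
                          h1$eaf, h1$beta_exp, h1$se_exp, h1$pval_exp,
                          h1$n_exp)
    out2 <- make_sumstats(h1$snp, h1$effect_allele, h1$other_allele,
                          h1$eaf_out, h1$beta_out, h1$se_out, h1$pval_out,
                          h1$n_out)
    h2 <- harmonize(exp2, out2)
    expect_equal(h2$beta_out, h1$beta_out)
    expect_equal(h2$eaf_out, h1$eaf_out)
    expect_equal(nrow(exclusions(h2)), 0)

    # swapping outcome alleles then harmonizing restores beta_out
    out_sw <- sim$outcome
    tmp <- out_sw$effect_allele
    out_sw$effect_allele <- out_sw$other_allele
    out_sw$other_allele <- tmp
    out_sw$beta <- -out_sw$beta
    out_sw$eaf <- 1 - out_sw$eaf
    h3 <- harmonize(sim$exposure, out_sw)
    expect_equal(h3$beta_out, h1$beta_out)

    # accounting: retained + excluded = intersection size
    expect_equal(nrow(h1) + nrow(exclusions(h1)),
                 length(intersect(sim$exposure$snp, sim$outcome$snp)))
  }
})
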