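test_that("wald_ratio matches the delta method and rejects null instruments", {
  expect_equal(wald_ratio(0.1, 0.01, 0.2, 0.05)$ratio, 2)
  expect_equal(wald_ratio(0.1, 0.01, 0.2, 0.05)$se, 0.5)
  w0 <- wald_ratio(0.1, 0.01, 0, 0.05)
  expect_equal(w0$ratio, 0)
  expect_equal(w0$se, 0.5)
  expect_error(wald_ratio(0, 0.01, 0.2, 0.05), "null instrument")
  # second-order correction is small for strong instruments (F > 30)
  h <- sim_h(31)
  f_per_snp <- (h$beta_exp / h$se_exp)^2
  strong <- f_per_snp > 30
  w1 <- wald_ratio(h$beta_exp[strong], h$se_exp[strong],
                   h$beta_out[strong], h$se_out[strong])
  w2 <- wald_ratio(h$beta_exp[strong], h$se_exp[strong],
                   h$beta_out[strong], h$se_out[strong], second_order = TRUE)
  expect_true(all(abs(w2$se - w1$se) / w1$se < 0.05))
})

test_that("IVW: degenerate cases and the grid-minimization oracle", {
  # all ratios equal c: slope c, Q = 0, fixed = random
  h <- make_h(bx = c(0.1, 0.2, 0.05), by = 3 * c(0.1, 0.2, 0.05),
              byse = c(0.03, 0.05, 0.02))
  f <- mr_ivw(h, model = "fixed")
  r <- mr_ivw(h, model = "random")
  expect_equal(f$b, 3)
  expect_equal(attr(f, "heterogeneity")$Q, 0)
  expect_equal(f$se, r$se)  # floor at 1 makes random = fixed when Q = 0

  # single SNP under the relaxed fixed-model precondition = Wald ratio
  h1 <- make_h(bx = 0.1, by = 0.25, byse = 0.04)
  expect_equal(mr_ivw(h1, model = "fixed")$b, 2.5)
  expect_equal(mr_ivw(h1, model = "fixed")$se, 0.4)
  expect_error(mr_ivw(h1), "at least 2")

  # slope minimizes the weighted least-squares objective (grid oracle)
  h50 <- random_h(50, seed = 8)
  b_hat <- mr_ivw(h50, model = "fixed")$b
  w <- h50$beta_exp^2 / h50$se_out^2
  r50 <- h50$beta_out / h50$beta_exp
  obj <- function(s) sum(w * (r50 - s)^2)
  grid <- seq(b_hat - 0.5, b_hat + 0.5, length.out = 20001)
  b_grid <- grid[which.min(vapply(grid, obj, numeric(1)))]
  expect_lt(abs(b_hat - b_grid), 1e-3)  # grid resolution
  # closed-form identity: weighted mean of ratios
  expect_equal(b_hat, weighted.mean(r50, w), tolerance = 1e-12)
})

test_that("Egger recovers an exact linear law to machine precision", {
  bx <- c(0.05, 0.08, 0.12, 0.2, 0.3)
  a <- 0.013
  b <- 0.7
  h <- make_h(bx = bx, by = a + b * bx, byse = c(0.01, 0.02, 0.03, 0.01, 0.02))
  e <- mr_egger(h)
  expect_equal(e$b, b, tolerance = 1e-10)
  expect_equal(attr(e, "intercept")$intercept, a, tolerance = 1e-10)
  expect_error(mr_egger(make_h(bx = c(0.1, 0.2), by = c(0.1, 0.2),
                               byse = c(0.01, 0.01))), "at least 3")
})

test_that("weighted median: exact small cases and bootstrap SE", {
  # three equal-weight ratios (1, 2, 9) -> 2
  h <- make_h(bx = c(0.1, 0.1, 0.1), by = c(0.1, 0.2, 0.9),
              byse = c(0.05, 0.05, 0.05))
  wm <- mr_weighted_median(h, n_boot = 0)
  expect_equal(wm$b, 2)
  # equal ratios: estimate is that ratio, bootstrap SE small
  he <- make_h(bx = c(0.1, 0.2, 0.3), by = 2 * c(0.1, 0.2, 0.3),
               byse = c(0.001, 0.001, 0.001),
               bxse = c(1e-5, 1e-5, 1e-5))
  wme <- mr_weighted_median(he, n_boot = 300, seed = 1)
  expect_equal(wme$b, 2)
  expect_lt(wme$se, 0.05)
})

test_that("mode estimators find the majority cluster and match a grid oracle", {
  h <- make_h(bx = rep(0.1, 4), by = c(0.1, 0.1, 0.1, 0.5),
              byse = rep(0.03, 4))
  expect_equal(mr_weighted_mode(h, n_boot = 0)$b, 1, tolerance = 0.1)
  expect_equal(mr_simple_mode(h, n_boot = 0)$b, 1, tolerance = 0.1)

  # brute-force weighted kernel density maximization oracle
  set.seed(3)
  h2 <- random_h(30, seed = 13)
  r <- h2$beta_out / h2$beta_exp
  se_r <- h2$se_out / abs(h2$beta_exp)
  w <- (1 / se_r^2) / sum(1 / se_r^2)
  bw <- 0.9 * min(sd(r), mad(r)) * length(r)^(-1 / 5)
  grid <- seq(min(r) - 3 * bw, max(r) + 3 * bw, length.out = 40001)
  dens <- vapply(grid, function(x) sum(w * dnorm((x - r) / bw)), numeric(1))
  oracle <- grid[which.max(dens)]
  expect_equal(mr_weighted_mode(h2, n_boot = 0)$b, oracle, tolerance = 0.02)

  # tiny-SE minority cluster pulls the weighted but not the simple mode
  h3 <- make_h(bx = rep(0.1, 10),
               by = c(rep(0.1, 7), rep(0.5, 3)),
               byse = c(rep(0.05, 7), rep(0.001, 3)))
  wmode <- mr_weighted_mode(h3, n_boot = 0)$b
  smode <- mr_simple_mode(h3, n_boot = 0)$b
  expect_equal(smode, 1, tolerance = 0.15)
  expect_equal(wmode, 5, tolerance = 0.15)
})

test_that("estimators are scale- and sign-equivariant", {
  for (seed in 1:3) {
    h <- sim_h(100 + seed, n_snps = 40)
    base <- list(ivw = mr_ivw(h, model = "fixed"),
                 egger = mr_egger(h),
                 wm = mr_weighted_median(h, n_boot = 0),
                 mode = mr_weighted_mode(h, n_boot = 0))
    # scale: multiply outcome side by c
    cc <- 2.7
    hs <- as_harmonized(dplyr::mutate(h, beta_out = cc * beta_out,
                                      se_out = cc * se_out))
    expect_equal(mr_ivw(hs, model = "fixed")$b, cc * base$ivw$b)
    expect_equal(mr_ivw(hs, model = "fixed")$se, cc * base$ivw$se)
    expect_equal(mr_egger(hs)$b, cc * base$egger$b)
    expect_equal(mr_weighted_median(hs, n_boot = 0)$b, cc * base$wm$b)
    expect_equal(mr_weighted_mode(hs, n_boot = 0)$b, cc * base$mode$b,
                 tolerance = 1e-6)
    # sign: negate the exposure coding (re-orientation)
    hn <- as_harmonized(dplyr::mutate(h, beta_exp = -beta_exp,
                                      beta_out = -beta_out))
    expect_equal(mr_ivw(hn, model = "fixed")$b, base$ivw$b)
    expect_equal(mr_egger(hn)$b, base$egger$b)
    expect_equal(mr_weighted_median(hn, n_boot = 0)$b, base$wm$b)
  }
})

test_that("directional pleiotropy biases IVW more than Egger's slope", {
  reps <- 120
  errs <- vapply(seq_len(reps), function(i) {
    sim <- simulate_pair(recovery_config(3000 + i, n_snps = 60,
                                         pleio_frac = 0.4,
                                         pleio_mean = 0.04,
                                         pleio_sd = 0.01))
    h <- harmonize(sim$exposure, sim$outcome)
    c(ivw = abs(mr_ivw(h, model = "fixed")$b - 0.5),
      egger = abs(mr_egger(h)$b - 0.5))
  }, numeric(2))
  expect_lt(median(errs["egger", ]), median(errs["ivw", ]))
})

test_that("weighted median resists 30% invalid instruments better than IVW", {
  sim <- simulate_pair(recovery_config(77, n_snps = 50, pleio_frac = 0.3,
                                       pleio_mean = 0.08, pleio_sd = 0.01))
  h <- harmonize(sim$exposure, sim$outcome)
  wm <- mr_weighted_median(h, n_boot = 500, seed = 2)
  ivw <- mr_ivw(h, model = "fixed")
  expect_lt(abs(wm$b - 0.5), 2 * wm$se)
  expect_gt(abs(ivw$b - 0.5), 2 * ivw$se)
})

test_that("mr_fit bundles tidy/glance and unimodal clouds agree across methods", {
  h <- sim_h(55, n_snps = 80)
  fit <- mr_fit(h, n_boot = 200, seed = 4)
  td <- tidy(fit)
  expect_equal(nrow(td), 5)
  expect_equal(td$or, exp(td$b))
  gl <- glance(fit)
  expect_equal(gl$n_snp, 80)
  # symmetric unimodal ratio cloud: mode ~ median ~ IVW
  ests <- td$b[td$method %in% c("IVW", "Weighted median", "Weighted mode")]
  expect_lt(max(ests) - min(ests), 0.1)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
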