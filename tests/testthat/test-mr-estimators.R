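# The five causal estimators and their shared Wald-ratio kernel.

test_that("Wald ratios follow first-order arithmetic and match a raw recomputation", {
  tab <- make_iv_table(beta_exp = 0.10, beta_out = 0.05, se_out = 0.02)
  wr <- wald_ratios(tab)
  expect_equal(wr$ratio, 0.5)
  expect_equal(wr$se, 0.2)

  set.seed(5)
  tab2 <- make_iv_table(beta_exp = rnorm(10, 0.2, 0.05),
                        beta_out = rnorm(10, 0.02, 0.01),
                        se_exp = runif(10, 0.005, 0.02),
                        se_out = runif(10, 0.005, 0.02))
  wr2 <- wald_ratios(tab2)
  expect_equal(wr2$ratio, tab2$beta_out / tab2$beta_exp)
  expect_equal(wr2$se, tab2$se_out / abs(tab2$beta_exp))
  # second-order adds the exposure-uncertainty term
  wr2b <- wald_ratios(tab2, second_order = TRUE)
  expect_true(all(wr2b$se >= wr2$se))

  # zero exposure effects are excluded with a log entry
  tab3 <- make_iv_table(beta_exp = c(0.1, 0), beta_out = c(0.05, 0.05))
  wr3 <- wald_ratios(tab3)
  expect_equal(nrow(wr3), 1)
  expect_equal(attr(wr3, "excluded"), "iv2")
})

test_that("IVW matches the hand-computed weighted mean and inflates only under heterogeneity", {
  tab <- make_iv_table(beta_exp = 1, beta_out = c(0.1, 0.2, 0.3),
                       se_out = 0.1)
  f <- mr_ivw(tab)
  expect_equal(f$beta, 0.2)
  expect_equal(f$se, 0.1 / sqrt(3))  # Q/(k-1) = 1: no inflation
  expect_equal(f$extra$inflation, 1)

  # homogeneous ratios: estimate equals the common value, inflation 1
  hom <- make_iv_table(beta_exp = 1, beta_out = rep(0.1, 4), se_out = 0.05)
  fh <- mr_ivw(hom)
  expect_equal(fh$beta, 0.1)
  expect_equal(fh$extra$inflation, 1)

  # gross heterogeneity inflates the SE multiplicatively
  het <- make_iv_table(beta_exp = 1, beta_out = c(0.1, 0.5, 0.9, 1.5),
                       se_out = 0.05)
  fhet <- mr_ivw(het)
  expect_gt(fhet$extra$inflation, 1)
  expect_equal(fhet$se, fhet$extra$se_fixed * fhet$extra$inflation)

  expect_error(mr_ivw(make_iv_table(beta_exp = 1, beta_out = 0.1)),
               "insufficient-instruments")
})

test_that("Egger regression is exact on a line and matches weighted least squares", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  tab <- make_iv_table(beta_exp = bx, beta_out = 0.02 + 0.3 * bx,
                       se_out = 0.05)
  f <- mr_egger(tab)
  expect_equal(f$beta, 0.3, tolerance = 1e-10)
  expect_equal(f$extra$intercept, 0.02, tolerance = 1e-10)

  # minimal k = 3 case against lm's normal-equations solution
  set.seed(8)
  tab3 <- make_iv_table(beta_exp = c(0.1, 0.25, 0.4),
                        beta_out = c(0.08, 0.02, 0.16),
                        se_out = c(0.01, 0.02, 0.015))
  f3 <- mr_egger(tab3)
  o <- lm(beta_out ~ beta_exp, data = tab3, weights = 1 / tab3$se_out^2)
  expect_equal(f3$beta, unname(coef(o)[2]), tolerance = 1e-10)
  expect_equal(f3$extra$intercept, unname(coef(o)[1]), tolerance = 1e-10)
  # with overdispersion above 1 the SEs match lm's weighted solution
  sm <- summary(o)
  if (sm$sigma^2 > 1) {
    expect_equal(f3$se, sm$coefficients[2, 2], tolerance = 1e-8)
    expect_equal(f3$extra$se_intercept, sm$coefficients[1, 2],
                 tolerance = 1e-8)
  }

  # orientation: flipping an instrument pair's signs changes nothing
  tab_f <- tab
  tab_f$beta_exp[2] <- -tab_f$beta_exp[2]
  tab_f$beta_out[2] <- -tab_f$beta_out[2]
  ff <- mr_egger(tab_f)
  expect_equal(ff$beta, f$beta)
  expect_equal(ff$extra$intercept, f$extra$intercept)

  expect_error(mr_egger(make_iv_table(beta_exp = c(1, 1),
                                      beta_out = c(0.1, 0.2))),
               "insufficient-instruments")
})

test_that("directional pleiotropy biases IVW upward while Egger absorbs it", {
  ivw_b <- egger_b <- egger_i <- numeric(60)
  for (r in 1:60) {
    s <- simulate_mr_scenario(mr_scenario(
      k_iv = 30, beta_causal = 0.1, pleiotropy_mode = "directional",
      pleiotropy_mean = 0.05, pleiotropy_sd = 0, seed = 700 + r))
    hp <- harmonize_pair(s$exposure, s$outcome)
    ivw_b[r] <- mr_ivw(hp)$beta
    fe <- mr_egger(hp)
    egger_b[r] <- fe$beta
    egger_i[r] <- fe$extra$intercept
  }
  expect_gt(mean(ivw_b), 0.4)                 # heavily biased upward
  expect_lt(abs(mean(egger_i) - 0.05), 0.01)  # intercept recovers the shift
  expect_lt(abs(mean(egger_b) - 0.1), 0.05)   # slope recovers the effect
})

test_that("weighted median interpolates the cumulative-weight boundary", {
  tab <- make_iv_table(beta_exp = 1, beta_out = c(0.1, 0.2, 0.9),
                       se_out = 0.1)
  expect_equal(mr_weighted_median(tab, n_boot = 50, seed = 1)$beta, 0.2)

  # 60% of the weight at 0.1, 40% at 0.9: cumulative mid-weights
  # (0.15, 0.45, 0.80) cross 0.5 between the second and third ratio
  tab2 <- make_iv_table(beta_exp = 1, beta_out = c(0.1, 0.1, 0.9),
                        se_out = 1 / sqrt(c(0.3, 0.3, 0.4)))
  got <- mr_weighted_median(tab2, n_boot = 50, seed = 1)$beta
  expect_equal(got, 0.1 + 0.8 * (0.5 - 0.45) / (0.8 - 0.45))

  expect_error(mr_weighted_median(make_iv_table(beta_exp = 1,
                                                beta_out = c(0.1, 0.2))),
               "insufficient-instruments")
})

test_that("mode estimators find majority clusters and respect precision weights", {
  # degenerate density: the common ratio is returned for both modes
  tab0 <- make_iv_table(beta_exp = 1, beta_out = rep(0.25, 5), se_out = 0.1)
  expect_equal(mr_mode(tab0, weighted = FALSE, n_boot = 50, seed = 1)$beta, 0.25)
  expect_equal(mr_mode(tab0, weighted = TRUE, n_boot = 50, seed = 1)$beta, 0.25)

  # 7 ratios near 0.1 and 3 near 0.9: the majority cluster wins
  set.seed(9)
  ratios <- c(0.1 + rnorm(7, 0, 0.005), 0.9 + rnorm(3, 0, 0.005))
  tab <- make_iv_table(beta_exp = 1, beta_out = ratios, se_out = 0.05)
  expect_lt(abs(mr_mode(tab, n_boot = 50, seed = 1)$beta - 0.1), 0.05)

  # give the 0.9 cluster 10x the precision: the weighted mode moves there
  # while the simple mode stays with the majority count
  tab_w <- tab
  tab_w$se_out <- c(rep(0.05, 7), rep(0.005, 3))
  expect_lt(abs(mr_mode(tab_w, weighted = FALSE, n_boot = 50, seed = 1)$beta - 0.1),
            0.05)
  expect_lt(abs(mr_mode(tab_w, weighted = TRUE, n_boot = 50, seed = 1)$beta - 0.9),
            0.05)

  expect_error(mr_mode(make_iv_table(beta_exp = 1, beta_out = c(0.1, 0.2))),
               "insufficient-instruments")
})

test_that("all five methods coincide exactly in the noiseless limit", {
  s <- simulate_mr_scenario(mr_scenario(k_iv = 10, beta_causal = 0.2,
                                        noise_scale = 0, seed = 14))
  hp <- harmonize_pair(s$exposure, s$outcome)
  res <- mr_all(hp, n_boot = 50, seed = 3)
  expect_equal(res$beta, rep(0.2, 5), tolerance = 1e-10)
})

test_that("estimates are sign-equivariant and odds ratios exponentiate consistently", {
  s <- simulate_mr_scenario(mr_scenario(k_iv = 12, beta_causal = 0.15,
                                        seed = 15))
  hp <- harmonize_pair(s$exposure, s$outcome)
  res <- mr_all(hp, n_boot = 100, seed = 4)
  neg <- hp
  neg$pairs$beta_out <- -neg$pairs$beta_out
  res_neg <- mr_all(neg, n_boot = 100, seed = 4)
  expect_equal(res_neg$beta, -res$beta, tolerance = 1e-8)

  expect_equal(res$OR, exp(res$beta))
  expect_equal(res$CI_low, exp(res$beta + qnorm(0.025) * res$se))
  expect_equal(res$CI_high, exp(res$beta + qnorm(0.975) * res$se))
  expect_true(all(res$CI_low < res$CI_high))

  # bootstrap SEs reproduce under the same seed
  res2 <- mr_all(hp, n_boot = 100, seed = 4)
  expect_identical(res$se, res2$se)
})

test_that("scatter export carries the per-instrument points and fitted lines", {
  s <- simulate_mr_scenario(mr_scenario(k_iv = 6, seed = 16))
  hp <- harmonize_pair(s$exposure, s$outcome)
  res <- mr_all(hp, n_boot = 50, seed = 5)
  sc <- mr_scatter_data(hp, res)
  expect_equal(nrow(sc$points), 6)
  expect_equal(sc$lines$slope, res$beta)
  expect_equal(sum(sc$lines$intercept != 0), 1)  # only Egger has one
})
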