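# Staged instrument selection: clumping, proxy search, and the full
# protocol with provenance accounting.

test_that("clumping keeps single and dominant candidates", {
  p <- simulate_panel(panel_config(n_ind = 300, m_snps = 4, block_size = 1,
                                   within_block_r = 0, seed = 1))
  one <- data.frame(snp_id = "rs1", chrom = "1", pos = 1e4, pvalue = 1e-6,
                    stringsAsFactors = FALSE)
  expect_equal(clump(one, p)$kept$snp_id, "rs1")

  # two perfectly correlated candidates: only the smaller p survives
  g <- p$geno
  g <- cbind(g, rs_dup = g[, "rs1"])
  pd <- make_panel(g, pos = c(p$variants$pos, 1.1e4))
  cand <- data.frame(snp_id = c("rs1", "rs_dup"), chrom = "1",
                     pos = c(1e4, 1.1e4), pvalue = c(1e-8, 1e-6),
                     stringsAsFactors = FALSE)
  cl <- clump(cand, pd)
  expect_equal(cl$kept$snp_id, "rs1")
  expect_equal(cl$removed$snp_id, "rs_dup")
  expect_equal(cl$removed$index_snp, "rs1")

  # candidates absent from the panel are kept with the no-LD flag
  cand2 <- rbind(cand, data.frame(snp_id = "rs_missing", chrom = "1",
                                  pos = 1.2e4, pvalue = 1e-7))
  cl2 <- clump(cand2, pd)
  expect_true("rs_missing" %in% cl2$kept$snp_id)
  expect_true(cl2$kept$no_ld_info[cl2$kept$snp_id == "rs_missing"])
})

test_that("greedy clumping matches an independent brute-force oracle", {
  for (seed in 1:5) {
    p <- simulate_panel(panel_config(n_ind = 150, m_snps = 20, block_size = 5,
                                     within_block_r = 0.7, seed = seed))
    set.seed(seed + 100)
    cand <- data.frame(snp_id = p$variants$snp_id, chrom = p$variants$chrom,
                       pos = p$variants$pos,
                       pvalue = runif(20, 1e-10, 1e-5),
                       stringsAsFactors = FALSE)
    got <- sort(clump(cand, p, r2_thresh = 0.1, distance_kb = 10000)$kept$snp_id)
    want <- clump_oracle(cand, p$geno, r2_thresh = 0.1, distance_bp = 1e7)
    expect_equal(got, want)
  }
})

test_that("proxy search finds the best in-LD substitute with deterministic ties", {
  p <- simulate_panel(panel_config(n_ind = 200, m_snps = 5, block_size = 5,
                                   within_block_r = 0.5, seed = 3))
  g <- cbind(p$geno, rs_dup = p$geno[, "rs2"])
  pd <- make_panel(g, pos = c(p$variants$pos, 9e4))
  target <- make_sumstats(c("rs_dup", "rs4"), beta = c(0.1, 0.1), se = 0.02)
  pr <- find_proxy("rs2", target, pd, r2_min = 0.8)
  expect_equal(pr$proxy, "rs_dup")
  expect_equal(pr$r2, 1)
  expect_equal(pr$r_sign, 1)

  # nothing above the threshold
  p0 <- simulate_panel(panel_config(n_ind = 500, m_snps = 5, block_size = 1,
                                    within_block_r = 0, seed = 4))
  target0 <- as_sumstats(p0$variants[, "snp_id", drop = FALSE] |>
                           transform(effect_allele = "A", other_allele = "G",
                                     beta = 0.1, se = 0.02))
  expect_true(is.na(find_proxy("rs1", target0, p0, r2_min = 0.8)$proxy))
  # absent from the panel
  expect_equal(find_proxy("zz1", target0, p0)$reason, "absent_from_panel")

  # exhaustive-search oracle on a block panel
  pb <- simulate_panel(panel_config(n_ind = 150, m_snps = 10, block_size = 10,
                                    within_block_r = 0.6, seed = 5))
  tgt <- as_sumstats(transform(pb$variants[-1, "snp_id", drop = FALSE],
                               effect_allele = "A", other_allele = "G",
                               beta = 0.1, se = 0.02))
  pr2 <- find_proxy("rs1", tgt, pb, r2_min = 0)
  r2_all <- as.vector(cor(pb$geno[, "rs1"], pb$geno[, -1]))^2
  expect_equal(pr2$proxy, colnames(pb$geno)[-1][which.max(r2_all)])
  expect_equal(pr2$r2, max(r2_all))
})

test_that("the staged protocol attributes every exclusion to its step", {
  s <- simulate_mr_scenario(mr_scenario(k_iv = 20,
                                        n_palindromic_intermediate = 1,
                                        seed = 21))
  confounders <- c("iv5", "iv9")  # non-palindromic planted instruments
  iv <- select_instruments(s$exposure, s$outcome, panel = NULL,
                           cfg = iv_config(confounder_snps = confounders))
  expect_equal(iv$k, 17)
  expect_equal(sum(iv$exclusions$step == 4), 2)
  expect_setequal(iv$exclusions$snp_id[iv$exclusions$step == 4], confounders)
  expect_equal(sum(iv$exclusions$step == 5), 1)
  expect_equal(iv$exclusions$snp_id[iv$exclusions$step == 5], "iv1")
  # conservation: kept + excluded = candidates passing step 1
  expect_equal(iv$k + nrow(iv$exclusions), iv$n_candidates)
  expect_equal(anyDuplicated(c(iv$instruments$snp_id, iv$exclusions$snp_id)), 0)
})

test_that("outcome-associated instruments are excluded at step 3", {
  s <- simulate_mr_scenario(mr_scenario(k_iv = 10, beta_causal = 0.1,
                                        seed = 31))
  out <- s$outcome$records
  out$pvalue[out$snp_id %in% c("iv3", "iv7")] <- 1e-8
  outcome <- as_sumstats(out, trait = "outcome")
  iv <- select_instruments(s$exposure, outcome, panel = NULL)
  expect_equal(iv$k, 8)
  expect_setequal(iv$exclusions$snp_id[iv$exclusions$step == 3],
                  c("iv3", "iv7"))
})

test_that("no candidate below the exposure threshold is a fatal step-1 error", {
  weak <- make_sumstats(c("rs1", "rs2"), beta = c(0.01, 0.01), se = 0.02)
  out <- make_sumstats(c("rs1", "rs2"), beta = c(0.01, 0.01), se = 0.02)
  expect_error(select_instruments(weak, out), "step 1")
})

test_that("instruments missing from the outcome are proxied or logged", {
  s <- simulate_mr_scenario(mr_scenario(k_iv = 6, seed = 41))
  # drop iv2 from the outcome; give the panel a perfect proxy for it
  out <- s$outcome$records
  proxy_rec <- out[out$snp_id == "iv2", ]
  proxy_rec$snp_id <- "proxy2"
  out <- rbind(out[out$snp_id != "iv2", ], proxy_rec)
  outcome <- as_sumstats(out, trait = "outcome")
  exp_geno <- simulate_panel(panel_config(n_ind = 100, m_snps = 1,
                                          block_size = 1, within_block_r = 0,
                                          seed = 42))$geno
  g <- cbind(iv2 = exp_geno[, 1], proxy2 = exp_geno[, 1])
  panel <- make_panel(g, pos = c(4e7, 4.1e7))
  iv <- select_instruments(s$exposure, outcome, panel)
  expect_equal(iv$k, 6)
  row <- iv$instruments[iv$instruments$snp_id == "iv2", ]
  expect_true(row$proxy_used)
  expect_equal(row$proxy_snp, "proxy2")
  expect_equal(row$beta_out,
               outcome$records$beta[outcome$records$snp_id == "proxy2"])
  # exposure statistics are inherited from the original instrument
  expect_equal(row$beta_exp,
               s$exposure$records$beta[s$exposure$records$snp_id == "iv2"])

  # without a panel the missing instrument is logged at step 6
  iv2 <- select_instruments(s$exposure, outcome, panel = NULL)
  expect_equal(iv2$k, 5)
  expect_match(iv2$exclusions$reason[iv2$exclusions$step == 6],
               "missing_from_outcome")
})

test_that("selection is a fixed point on its own kept set", {
  s <- simulate_mr_scenario(mr_scenario(k_iv = 15,
                                        n_palindromic_intermediate = 2,
                                        seed = 51))
  iv <- select_instruments(s$exposure, s$outcome)
  sub <- function(ss, ids) as_sumstats(
    ss$records[ss$records$snp_id %in% ids, ], trait = ss$trait,
    n_default = ss$n_default)
  iv2 <- select_instruments(sub(s$exposure, iv$instruments$snp_id),
                            sub(s$outcome, iv$instruments$snp_id))
  expect_equal(iv2$instruments$snp_id, iv$instruments$snp_id)
  expect_equal(iv2$instruments$beta_out, iv$instruments$beta_out)
  expect_equal(nrow(iv2$exclusions), 0)
})

test_that("tightening thresholds never grows the kept set", {
  b <- simulate_screen_battery(screen_battery_config(seed = 61))
  expo <- b$exposures[[b$truth$signal]]
  kept <- sapply(c(1e-5, 1e-6, 1e-7, 1e-8), function(pmax) {
    tryCatch(select_instruments(expo, b$outcome, b$panel,
                                iv_config(p_exposure_max = pmax))$k,
             error = function(e) 0L)
  })
  expect_true(all(diff(kept) <= 0))

  s <- simulate_mr_scenario(mr_scenario(k_iv = 12, beta_causal = 0.4,
                                        seed = 62))
  kept_out <- sapply(c(1e-5, 1e-4, 1e-3, 1e-2), function(pmax) {
    tryCatch(select_instruments(s$exposure, s$outcome, NULL,
                                iv_config(p_outcome_max = pmax))$k,
             error = function(e) 0L)
  })
  # a stricter outcome screen (larger exclusion threshold) keeps no more
  expect_true(all(diff(kept_out) <= 0))
})

test_that("instrument sets serialize with thresholds echoed in the log", {
  s <- simulate_mr_scenario(mr_scenario(k_iv = 5, seed = 71))
  iv <- select_instruments(s$exposure, s$outcome)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_iv_set(iv, path)
  expect_true(file.exists(paste0(path, ".log")))
  hdr <- readLines(paste0(path, ".log"))
  expect_match(hdr, "p_exposure_max\t1e-05", all = FALSE)
  tab <- read.delim(path)
  expect_equal(nrow(tab), iv$k)
  f <- iv_strength(iv)
  expect_true(all(f$f > qchisq(1 - 1e-5, 1)))
})
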