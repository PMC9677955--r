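# Reading, validation and pairwise harmonization of GWAS summary
# statistics.

test_that("well-formed tables read back identically, with dialect mapping", {
  df <- make_records(c("rs1", "rs2", "rs3"), beta = c(0.1, -0.2, 0.05),
                     se = c(0.02, 0.03, 0.01), pvalue = NA)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  ss <- read_sumstats(path, trait = "t")
  expect_s3_class(ss, "sumstats")
  expect_equal(n_variants(ss), 3)
  expect_equal(ss$records$beta, df$beta)
  expect_equal(nrow(ss$drops), 0)

  # a foreign column dialect maps onto the standard names
  names(df) <- c("variant", "chr", "bp", "A1", "A2", "freq", "b", "stderr",
                 "p", "N")
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  dialect <- c(snp_id = "variant", chrom = "chr", pos = "bp",
               effect_allele = "A1", other_allele = "A2", eaf = "freq",
               beta = "b", se = "stderr", pvalue = "p", n = "N")
  ss2 <- read_sumstats(path, dialect = dialect)
  expect_equal(ss2$records$snp_id, c("rs1", "rs2", "rs3"))
  expect_equal(ss2$records$beta, ss$records$beta)

  expect_error(read_sumstats(path, dialect = c(beta = "nonexistent")),
               "format error")
})

test_that("invariant violations are dropped and logged; lower-case alleles normalize", {
  df <- make_records(c("rs1", "rs2", "rs3", "rs4", "rs5"),
                     beta = c(0.1, 0.2, 0.1, 0.1, 0.1),
                     se = c(0.02, 0, 0.02, 0.02, 0.02))
  df$effect_allele <- c("a", "A", "A", "N", "A")
  df$other_allele <- c("t", "G", "A", "G", "G")
  ss <- as_sumstats(df)
  # rs2 (se = 0), rs3 (identical alleles), rs4 (non-ACGT) dropped
  expect_equal(n_variants(ss), 2)
  expect_setequal(ss$drops$snp_id, c("rs2", "rs3", "rs4"))
  expect_equal(ss$drops$reason[ss$drops$snp_id == "rs2"], "nonpositive_se")
  # lower-case a/t was upper-cased and accepted
  expect_equal(ss$records$effect_allele[ss$records$snp_id == "rs1"], "A")
  expect_equal(ss$records$other_allele[ss$records$snp_id == "rs1"], "T")
  # every dropped variant appears exactly once in the log
  expect_equal(anyDuplicated(ss$drops$snp_id), 0)

  expect_error(as_sumstats(make_records("rs1", beta = 0.1, se = 0)),
               "empty-input")
  expect_error(as_sumstats(data.frame(snp_id = "rs1", beta = 0.1)),
               "missing mandatory column")
})

test_that("reported p-values inconsistent with beta/se are flagged, not altered", {
  df <- make_records(c("rs1", "rs2"), beta = c(0.1, 0.1), se = c(0.05, 0.05),
                     pvalue = c(2 * pnorm(-2), 0.5))
  ss <- as_sumstats(df)
  expect_equal(ss$records$pvalue[2], 0.5)  # left as reported
  expect_match(ss$notes, "disagree", all = FALSE)
  # missing p-values are filled from the z-score
  df$pvalue <- NA
  ss2 <- as_sumstats(df)
  expect_equal(ss2$records$pvalue, rep(2 * pnorm(-2), 2))
})

test_that("palindromic and intermediate-frequency flags follow the allele pair and band", {
  f <- is_palindromic(c("A", "A", "G", "C"), c("T", "G", "C", "G"),
                      eaf = c(0.50, 0.50, 0.10, NA))
  expect_equal(f$palindromic, c(TRUE, FALSE, TRUE, TRUE))
  # 0.50 inside the band; 0.10 outside; missing eaf treated intermediate
  expect_equal(f$intermediate, c(TRUE, FALSE, FALSE, TRUE))
})

test_that("harmonization aligns swapped, complementary and mismatched allele frames", {
  exp <- make_sumstats(c("rs1", "rs2", "rs3"), beta = c(0.10, 0.10, 0.10),
                       se = 0.02, eaf = 0.3)
  out_rec <- make_records(c("rs1", "rs2", "rs3"), beta = c(0.05, 0.05, 0.05),
                          se = 0.02, eaf = 0.7)
  out_rec$effect_allele <- c("G", "T", "A")  # swap, strand complement, mismatch
  out_rec$other_allele <- c("A", "C", "C")
  out <- as_sumstats(out_rec)
  hp <- harmonize_pair(exp, out)
  expect_equal(hp$pairs$snp_id, c("rs1", "rs2"))
  expect_equal(hp$pairs$beta_out[hp$pairs$snp_id == "rs1"], -0.05)
  expect_equal(hp$pairs$action[hp$pairs$snp_id == "rs1"], "flip")
  # T/C is the strand complement of A/G: aligned without sign change
  expect_equal(hp$pairs$beta_out[hp$pairs$snp_id == "rs2"], 0.05)
  expect_equal(hp$log$snp_id, "rs3")
  expect_equal(hp$log$reason, "allele_mismatch")

  expect_error(harmonize_pair(exp, make_sumstats("zz9", beta = 1, se = 1)),
               "empty-overlap")
})

test_that("palindromic variants drop when intermediate and orient by frequency otherwise", {
  exp_rec <- make_records(c("rs1", "rs2", "rs3"), beta = 0.1, se = 0.02,
                          eaf = c(0.50, 0.10, 0.10))
  exp_rec$effect_allele <- "A"; exp_rec$other_allele <- "T"
  out_rec <- exp_rec
  out_rec$beta <- 0.05
  # rs2: same labels, frequency on the same side -> keep
  # rs3: same labels but frequency on the opposite side -> flip
  out_rec$eaf <- c(0.50, 0.12, 0.88)
  hp <- harmonize_pair(as_sumstats(exp_rec), as_sumstats(out_rec))
  expect_equal(hp$log$snp_id, "rs1")
  expect_equal(hp$log$reason, "palindromic_intermediate")
  expect_equal(hp$pairs$beta_out[hp$pairs$snp_id == "rs2"], 0.05)
  expect_equal(hp$pairs$beta_out[hp$pairs$snp_id == "rs3"], -0.05)

  # missing frequency on either side is a conservative drop
  out_rec$eaf <- c(0.2, NA, 0.12)
  hp2 <- harmonize_pair(as_sumstats(exp_rec), as_sumstats(out_rec))
  expect_true(all(c("rs1", "rs2") %in% hp2$log$snp_id))
})

test_that("harmonization is idempotent and sign-flips are involutive", {
  sim <- simulate_bivariate_gwas(
    synthetic_ld_scores(300, seed = 7),
    bivariate_gwas_config(scramble_alleles = TRUE, seed = 42))
  hp <- harmonize_pair(sim$ss1, sim$ss2)
  # re-harmonizing the harmonized pair changes nothing
  mk <- function(p, beta, se, pv) {
    as_sumstats(data.frame(snp_id = p$snp_id, effect_allele = p$ea,
                           other_allele = p$oa, eaf = p$eaf, beta = beta,
                           se = se, pvalue = pv, stringsAsFactors = FALSE))
  }
  hp2 <- harmonize_pair(mk(hp$pairs, hp$pairs$beta_exp, hp$pairs$se_exp, hp$pairs$p_exp),
                        mk(hp$pairs, hp$pairs$beta_out, hp$pairs$se_out, hp$pairs$p_out))
  expect_equal(hp2$pairs$beta_out, hp$pairs$beta_out)
  expect_equal(hp2$pairs$beta_exp, hp$pairs$beta_exp)
  expect_equal(nrow(hp2$log), 0)
  expect_true(all(hp2$pairs$action == "keep"))

  # flipping both input allele orders returns the original aligned betas
  flip_ss <- function(ss) {
    r <- ss$records
    tmp <- r$effect_allele
    r$effect_allele <- r$other_allele
    r$other_allele <- tmp
    r$beta <- -r$beta
    r$eaf <- 1 - r$eaf
    as_sumstats(r, trait = ss$trait)
  }
  hp3 <- harmonize_pair(flip_ss(sim$ss1), flip_ss(sim$ss2))
  shared <- intersect(hp$pairs$snp_id, hp3$pairs$snp_id)
  m1 <- match(shared, hp$pairs$snp_id)
  m3 <- match(shared, hp3$pairs$snp_id)
  # both frames describe the same association: products are preserved
  expect_equal(hp3$pairs$beta_exp[m3] * hp3$pairs$beta_out[m3],
               hp$pairs$beta_exp[m1] * hp$pairs$beta_out[m1])
  expect_equal(abs(hp3$pairs$beta_out[m3]), abs(hp$pairs$beta_out[m1]))

  # exclusion log accounting: every shared variant is kept or logged once
  shared_all <- intersect(sim$ss1$records$snp_id, sim$ss2$records$snp_id)
  expect_equal(nrow(hp$pairs) + nrow(hp$log), length(shared_all))
  expect_equal(anyDuplicated(c(hp$pairs$snp_id, hp$log$snp_id)), 0)
})
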