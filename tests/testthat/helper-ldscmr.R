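# Shared fixture builders. Everything is generated in code; no stored data.

# Quick summary-statistics records table with sensible defaults.
make_records <- function(snp_id, beta, se,
                         effect_allele = "A", other_allele = "G",
                         eaf = 0.3, pvalue = NA_real_, n = 10000,
                         chrom = "1", pos = seq_along(snp_id) * 1e4) {
  data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
             effect_allele = effect_allele, other_allele = other_allele,
             eaf = eaf, beta = beta, se = se, pvalue = pvalue, n = n,
             stringsAsFactors = FALSE)
}

make_sumstats <- function(...) as_sumstats(make_records(...))

# A ref_panel built directly from a dosage matrix.
make_panel <- function(geno, pos = seq_len(ncol(geno)) * 1e4,
                       chrom = "1", block = rep(1L, ncol(geno))) {
  snp_id <- colnames(geno) %||% sprintf("rs%d", seq_len(ncol(geno)))
  colnames(geno) <- snp_id
  structure(list(
    geno = geno,
    variants = data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                          maf = colMeans(geno) / 2, block = block,
                          stringsAsFactors = FALSE),
    config = NULL), class = "ref_panel")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Noise-free chi-square summary statistics lying exactly on the
# expectation line chi2 = n * h2 * l / m + n * a + 1.
exact_line_sumstats <- function(l, h2, n, m = length(l), a = 0,
                                trait = "exact") {
  chi2 <- n * h2 * l / m + n * a + 1
  z <- sqrt(chi2)
  as_sumstats(make_records(sprintf("rs%d", seq_along(l)),
                           beta = z / sqrt(n), se = 1 / sqrt(n), n = n),
              trait = trait)
}

# Bare instrument table for the MR estimators.
make_iv_table <- function(beta_exp, beta_out, se_exp = 0.01, se_out = 0.01,
                          snp_id = sprintf("iv%d", seq_along(beta_exp))) {
  data.frame(snp_id = snp_id, beta_exp = beta_exp, se_exp = se_exp,
             beta_out = beta_out, se_out = se_out, stringsAsFactors = FALSE)
}

# Independent greedy clumping oracle, written as a direct transcription
# of the rule (keep lowest p, discard in-window correlated neighbours).
clump_oracle <- function(cand, geno, r2_thresh, distance_bp) {
  remaining <- cand[order(cand$pvalue, cand$snp_id), ]
  kept <- character(0)
  while (nrow(remaining) > 0) {
    top <- remaining[1, ]
    kept <- c(kept, top$snp_id)
    remaining <- remaining[-1, , drop = FALSE]
    if (nrow(remaining) == 0) break
    drop <- logical(nrow(remaining))
    for (i in seq_len(nrow(remaining))) {
      r <- remaining[i, ]
      if (r$chrom == top$chrom && abs(r$pos - top$pos) <= distance_bp) {
        r2 <- stats::cor(geno[, top$snp_id], geno[, r$snp_id])^2
        drop[i] <- is.finite(r2) && r2 >= r2_thresh
      }
    }
    remaining <- remaining[!drop, , drop = FALSE]
  }
  sort(kept)
}
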