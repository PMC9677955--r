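# Synthetic reference panels and GWAS summary statistics with known
# ground truth: heritability, genetic correlation, confounding inflation,
# and Mendelian-randomization causal structure with planted pleiotropy.
#
# The bivariate generator is summary-statistics-first: it draws per-variant
# z-scores directly from the model
#   E[chi2_t | l_j] = N_t h2_t l_j / M + N_t a_t + 1
#   E[z1 z2 | l_j]  = sqrt(N1 N2) rg sqrt(h2_1 h2_2) l_j / M + c
# which is exact for the quantities LD score regression estimates, and
# keeps desk-scale variant counts feasible. An individual-level panel path
# exists for small oracle tests.

#' Reference-panel configuration
#'
#' @param n_ind Number of individuals.
#' @param m_snps Number of variants (must be divisible by `block_size`).
#' @param block_size Variants per LD block.
#' @param within_block_r Latent pairwise correlation inside a block, in
#'   `[0, 1)`. Realized genotype (dosage) correlation is attenuated
#'   relative to this latent value because dosages are discrete.
#' @param maf_range Interval from which per-variant allele frequencies are
#'   drawn.
#' @param seed Integer seed; panels are pure functions of the config.
#' @return A `panel_config` list.
#' @export
panel_config <- function(n_ind = 500, m_snps = 100, block_size = 10,
                         within_block_r = 0.5, maf_range = c(0.05, 0.5),
                         seed = 1) {
  if (m_snps %% block_size != 0) {
    stop("config error: m_snps must be divisible by block_size", call. = FALSE)
  }
  if (within_block_r < 0 || within_block_r >= 1) {
    stop("config error: within_block_r must be in [0, 1)", call. = FALSE)
  }
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop("config error: maf_range must satisfy 0 < lo <= hi <= 0.5", call. = FALSE)
  }
  structure(list(n_ind = n_ind, m_snps = m_snps, block_size = block_size,
                 within_block_r = within_block_r, maf_range = maf_range,
                 seed = seed), class = "panel_config")
}

#' Simulate a reference genotype panel with block LD
#'
#' Generates dosages 0/1/2 from two haplotypes per individual. Within a
#' block, haplotype indicators share a Gaussian-copula correlation of
#' `within_block_r`; blocks are independent. Monomorphic columns (possible
#' at small panel sizes) are repaired by flipping one haplotype so every
#' variant has nonzero variance.
#'
#' @param cfg A [panel_config()].
#' @return A `ref_panel`: list with `geno` (n_ind x m_snps dosage matrix,
#'   columns named by snp_id), `variants` (data.frame `snp_id`, `chrom`,
#'   `pos`, `maf`, `block`) and the generating config.
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "panel_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_ind; m <- cfg$m_snps; bs <- cfg$block_size
    r <- cfg$within_block_r
    n_blocks <- m %/% bs
    p <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
    geno <- matrix(0L, n, m)
    for (hap in 1:2) {
      # block-exchangeable latent normals: sqrt(r) * shared + sqrt(1-r) * own
      shared <- matrix(stats::rnorm(n * n_blocks), n, n_blocks)
      own <- matrix(stats::rnorm(n * m), n, m)
      blk <- rep(seq_len(n_blocks), each = bs)
      latent <- sqrt(r) * shared[, blk, drop = FALSE] + sqrt(1 - r) * own
      alleles <- sweep(stats::pnorm(latent), 2, p, `<`)
      geno <- geno + alleles
    }
    storage.mode(geno) <- "integer"
    # repair monomorphic columns so no variant has zero variance
    for (j in which(apply(geno, 2, function(g) length(unique(g)) == 1L))) {
      i <- 1 + (j %% n)
      geno[i, j] <- if (geno[i, j] == 0L) 1L else geno[i, j] - 1L
    }
    snp_id <- sprintf("rs%d", seq_len(m))
    colnames(geno) <- snp_id
    variants <- data.frame(
      snp_id = snp_id, chrom = "1", pos = seq_len(m) * 1e4,
      maf = colMeans(geno) / 2,
      block = rep(seq_len(n_blocks), each = bs),
      stringsAsFactors = FALSE)
    structure(list(geno = geno, variants = variants, config = cfg),
              class = "ref_panel")
  })
}

#' @export
print.ref_panel <- function(x, ...) {
  cat(sprintf("<ref_panel> %d individuals x %d variants (%d blocks)\n",
              nrow(x$geno), ncol(x$geno), max(x$variants$block)))
  invisible(x)
}

#' Write a reference panel as tab-separated text
#'
#' Writes the dosage matrix (individuals x variants, header row of
#' variant ids) and a sidecar variant table at `paste0(path, ".vars")`.
#' @param panel A `ref_panel`.
#' @param path Output path for the dosage matrix.
#' @export
write_panel <- function(panel, path) {
  data.table::fwrite(as.data.frame(panel$geno), path, sep = "\t", quote = FALSE)
  data.table::fwrite(panel$variants, paste0(path, ".vars"), sep = "\t",
                     quote = FALSE)
  invisible(path)
}

#' Read a reference panel written by [write_panel()]
#' @param path Path of the dosage matrix; the variant table is read from
#'   `paste0(path, ".vars")`.
#' @export
read_panel <- function(path) {
  geno <- as.matrix(data.table::fread(path, sep = "\t", data.table = FALSE))
  variants <- data.table::fread(paste0(path, ".vars"), sep = "\t",
                                data.table = FALSE)
  variants$snp_id <- as.character(variants$snp_id)
  variants$chrom <- as.character(variants$chrom)
  storage.mode(geno) <- "integer"
  structure(list(geno = geno, variants = variants, config = NULL),
            class = "ref_panel")
}

#' Synthetic per-variant LD scores
#'
#' Draws LD scores uniformly on `l_range` (minimum 1, the self-term of a
#' variant in linkage equilibrium). Used by the summary-statistics-first
#' generator when no panel is supplied.
#'
#' @param m Number of variants.
#' @param l_range Range of scores.
#' @param seed Integer seed.
#' @return An `ld_scores` data.frame (`snp_id`, `chrom`, `pos`, `L2`).
#' @export
synthetic_ld_scores <- function(m, l_range = c(1, 100), seed = 1) {
  with_seed(seed, {
    df <- data.frame(
      snp_id = sprintf("rs%d", seq_len(m)),
      chrom = "1",
      pos = seq_len(m) * 1e4,
      L2 = stats::runif(m, l_range[1], l_range[2]),
      stringsAsFactors = FALSE)
    structure(df, class = c("ld_scores", "data.frame"))
  })
}

#' Bivariate GWAS generator configuration
#'
#' @param h2_1,h2_2 Heritabilities of the two traits in `[0, 1]`.
#' @param rg_true Genetic correlation in `[-1, 1]`.
#' @param n1,n2 GWAS sample sizes.
#' @param a1,a2 Per-study confounding inflation `a >= 0`; the fitted
#'   regression intercept targets `N a + 1`.
#' @param cross_intercept Shared-sample covariance term added to
#'   `E[z1 z2]`; zero for non-overlapping cohorts (the default).
#' @param scramble_alleles When `TRUE`, the second study's allele frames
#'   are randomly swapped or strand-complemented (harmonization exercise).
#' @param seed Integer seed.
#' @export
bivariate_gwas_config <- function(h2_1 = 0.4, h2_2 = 0.3, rg_true = 0.5,
                                  n1 = 20000, n2 = 20000, a1 = 0, a2 = 0,
                                  cross_intercept = 0,
                                  scramble_alleles = FALSE, seed = 1) {
  if (h2_1 < 0 || h2_1 > 1 || h2_2 < 0 || h2_2 > 1) {
    stop("config error: heritabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(rg_true) > 1) {
    stop("config error: |rg_true| must be <= 1", call. = FALSE)
  }
  if (a1 < 0 || a2 < 0) stop("config error: a must be >= 0", call. = FALSE)
  structure(list(h2_1 = h2_1, h2_2 = h2_2, rg_true = rg_true, n1 = n1,
                 n2 = n2, a1 = a1, a2 = a2, cross_intercept = cross_intercept,
                 scramble_alleles = scramble_alleles, seed = seed),
            class = "bivariate_gwas_config")
}

# Internal: draw the z-score pair matrix for given LD scores under the
# expectation model. Returns an m x 2 matrix.
draw_bivariate_z <- function(l, m_total, cfg) {
  v1 <- cfg$n1 * cfg$h2_1 * l / m_total + cfg$n1 * cfg$a1 + 1
  v2 <- cfg$n2 * cfg$h2_2 * l / m_total + cfg$n2 * cfg$a2 + 1
  cv <- sqrt(cfg$n1 * cfg$n2) * cfg$rg_true * sqrt(cfg$h2_1 * cfg$h2_2) *
    l / m_total + cfg$cross_intercept
  resid <- v2 - cv^2 / v1
  if (any(resid < 0)) {
    stop("config error: infeasible covariance structure (|rg| too large ",
         "for the given heritabilities/intercepts)", call. = FALSE)
  }
  m <- length(l)
  u1 <- stats::rnorm(m)
  u2 <- stats::rnorm(m)
  z1 <- sqrt(v1) * u1
  z2 <- (cv / sqrt(v1)) * u1 + sqrt(resid) * u2
  cbind(z1, z2)
}

# Internal: wrap z-scores into a sumstats object with non-palindromic
# allele pairs and benign frequencies, so validation drops nothing.
z_to_sumstats <- function(snp_id, chrom, pos, z, n, trait, ea, oa, eaf) {
  beta <- z / sqrt(n)
  se <- rep(1 / sqrt(n), length(z))
  as_sumstats(data.frame(
    snp_id = snp_id, chrom = chrom, pos = pos,
    effect_allele = ea, other_allele = oa, eaf = eaf,
    beta = beta, se = se, pvalue = floored_p(z), n = n,
    stringsAsFactors = FALSE), trait = trait, n_default = n)
}

#' Simulate a pair of GWAS summary statistics under the LD-score model
#'
#' Draws per-variant z-score pairs whose first and second moments satisfy
#' the LD-score regression expectation model (see the package vignette),
#' then back-fills effect sizes as `z/sqrt(N)` with standard errors
#' `1/sqrt(N)`. Deterministic given the config seed.
#'
#' @param scores An `ld_scores` data.frame (e.g. [synthetic_ld_scores()]
#'   or [compute_ld_scores()]) or a `ref_panel` (scores are computed from
#'   it first).
#' @param cfg A [bivariate_gwas_config()].
#' @param m_total Total variant count `M` entering the expectation model;
#'   defaults to the number of scored variants.
#' @return List with `ss1`, `ss2` (both `sumstats`) and `truth` (the
#'   generating parameters).
#' @export
simulate_bivariate_gwas <- function(scores, cfg, m_total = NULL) {
  stopifnot(inherits(cfg, "bivariate_gwas_config"))
  if (inherits(scores, "ref_panel")) scores <- compute_ld_scores(scores)
  l <- scores$L2
  if (anyNA(l)) stop("LD scores must be available for all variants", call. = FALSE)
  m_total <- m_total %||% length(l)
  with_seed(cfg$seed, {
    z <- draw_bivariate_z(l, m_total, cfg)
    m <- length(l)
    # fixed non-palindromic frames; frequencies clear of the intermediate band
    ea1 <- rep(c("A", "C"), length.out = m)
    oa1 <- rep(c("G", "T"), length.out = m)
    eaf <- stats::runif(m, 0.10, 0.90)
    eaf <- ifelse(eaf > 0.40 & eaf < 0.60, eaf + 0.25, eaf)
    ss1 <- z_to_sumstats(scores$snp_id, scores$chrom, scores$pos, z[, 1],
                         cfg$n1, "trait1", ea1, oa1, eaf)
    ea2 <- ea1; oa2 <- oa1; beta2_sign <- rep(1, m); eaf2 <- eaf
    if (isTRUE(cfg$scramble_alleles)) {
      swap <- stats::runif(m) < 0.5
      comp <- stats::runif(m) < 0.5
      ea2[swap] <- oa1[swap]; oa2[swap] <- ea1[swap]
      beta2_sign[swap] <- -1
      eaf2[swap] <- 1 - eaf[swap]
      ea2[comp] <- complement_allele(ea2[comp])
      oa2[comp] <- complement_allele(oa2[comp])
    }
    ss2 <- z_to_sumstats(scores$snp_id, scores$chrom, scores$pos,
                         beta2_sign * z[, 2], cfg$n2, "trait2", ea2, oa2, eaf2)
    list(ss1 = ss1, ss2 = ss2,
         truth = list(h2_1 = cfg$h2_1, h2_2 = cfg$h2_2, rg = cfg$rg_true,
                      intercept_1 = cfg$n1 * cfg$a1 + 1,
                      intercept_2 = cfg$n2 * cfg$a2 + 1,
                      m_total = m_total))
  })
}

#' Mendelian-randomization scenario configuration
#'
#' Defines a two-sample MR data-generating process with `k_iv` genuine
#' instruments, a known causal effect, and optional violations of the
#' exclusion restriction (horizontal pleiotropy).
#'
#' @param k_iv Number of instruments (>= 3; >= 4 when the residual outlier
#'   test will be run).
#' @param beta_causal True causal effect of exposure on outcome.
#' @param pleiotropy_mode One of `"none"`, `"balanced"` (direct effects
#'   centred on zero), `"directional"` (centred on `pleiotropy_mean`),
#'   `"outlier"` (all zero except `n_outlier` planted outliers).
#' @param pleiotropy_sd Spread of direct effects for the balanced and
#'   directional modes.
#' @param pleiotropy_mean Mean direct effect in the directional mode.
#' @param n_outlier Number of planted outliers in the outlier mode.
#' @param outlier_multiple Outlier direct effect in units of the outcome
#'   standard error (a `10` shifts that instrument's Wald ratio by ten
#'   ratio standard errors).
#' @param frac_invalid Fraction of instruments carrying direct effects in
#'   the balanced/directional modes (1 = all, as in classical balanced
#'   pleiotropy; 0.4 reproduces a "40% invalid instruments" design).
#' @param n1,n2 Exposure and outcome GWAS sample sizes.
#' @param instrument_z_range Range of true exposure association z-scores
#'   `|b_x| sqrt(n1)`. The default (7, 14) emulates instruments passing a
#'   suggestive 1e-5 screen with modest strength; widen the lower bound
#'   upward (e.g. `c(70, 140)`) to study estimator properties in the
#'   strong-instrument regime where per-instrument ratio noise is
#'   negligible.
#' @param noise_scale Multiplier on estimation noise (0 gives noiseless
#'   summary statistics; 1 is the nominal sampling noise).
#' @param n_palindromic_intermediate Number of instruments generated as
#'   palindromic with allele frequency 0.5 (exercises harmonization
#'   exclusions).
#' @param m_null Additional null background variants present in both
#'   studies.
#' @param seed Integer seed.
#' @export
mr_scenario <- function(k_iv = 20, beta_causal = 0.1,
                        pleiotropy_mode = c("none", "balanced", "directional",
                                            "outlier"),
                        pleiotropy_sd = 0, pleiotropy_mean = 0.05,
                        n_outlier = 1, outlier_multiple = 10,
                        frac_invalid = 1, n1 = 20000, n2 = 20000,
                        instrument_z_range = c(7, 14),
                        noise_scale = 1, n_palindromic_intermediate = 0,
                        m_null = 0, seed = 1) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (k_iv < 3) stop("config error: k_iv must be >= 3", call. = FALSE)
  if (pleiotropy_mode == "outlier" && n_outlier >= k_iv) {
    stop("config error: n_outlier must be < k_iv", call. = FALSE)
  }
  structure(list(k_iv = k_iv, beta_causal = beta_causal,
                 pleiotropy_mode = pleiotropy_mode,
                 pleiotropy_sd = pleiotropy_sd,
                 pleiotropy_mean = pleiotropy_mean,
                 n_outlier = n_outlier, outlier_multiple = outlier_multiple,
                 frac_invalid = frac_invalid, n1 = n1, n2 = n2,
                 instrument_z_range = instrument_z_range,
                 noise_scale = noise_scale,
                 n_palindromic_intermediate = n_palindromic_intermediate,
                 m_null = m_null, seed = seed),
            class = "mr_scenario")
}

# Exposure p-value guarantee used by the scenario generator.
MR_EXPOSURE_P <- 1e-5

#' Simulate a two-sample MR scenario with known causal structure
#'
#' Generates exposure and outcome summary statistics for `k_iv`
#' instruments (plus optional null background variants). True exposure
#' effects are drawn with |z| large enough that every instrument's
#' estimated exposure p-value is below `1e-5` by construction (failing
#' draws are rejected and redrawn, deterministically under the seed).
#' Outcome effects are `beta_causal * b_x + alpha_j + noise`, where the
#' latent direct effects `alpha_j` follow the scenario's pleiotropy mode
#' and are stored in the truth record. Direct effects are planted in the
#' exposure-increasing-allele frame (so a directional mean shifts every
#' oriented instrument the same way) and recorded on the measured allele.
#'
#' Instruments are placed >= 20 Mb apart on one chromosome so they are
#' never removed by distance-based clumping.
#'
#' @param sc An [mr_scenario()].
#' @return List with `exposure`, `outcome` (both `sumstats`) and `truth`
#'   (`beta_causal`, per-instrument `b_x`, `alpha`, instrument ids,
#'   planted outlier ids).
#' @export
simulate_mr_scenario <- function(sc) {
  stopifnot(inherits(sc, "mr_scenario"))
  with_seed(sc$seed, {
    k <- sc$k_iv
    se_x <- 1 / sqrt(sc$n1)
    se_y <- 1 / sqrt(sc$n2)
    # true exposure effects: |z| in instrument_z_range, random sign
    zr <- sc$instrument_z_range
    b_x <- (stats::runif(k, zr[1], zr[2]) / sqrt(sc$n1)) *
      sample(c(-1, 1), k, TRUE)

    alpha <- rep(0, k)
    invalid <- rep(FALSE, k)
    if (sc$pleiotropy_mode %in% c("balanced", "directional")) {
      n_inv <- max(1L, round(sc$frac_invalid * k))
      invalid[sample.int(k, n_inv)] <- TRUE
      centre <- if (sc$pleiotropy_mode == "directional") sc$pleiotropy_mean else 0
      # direct effects are planted relative to the exposure-increasing
      # allele (the frame in which "directional" is defined), then mapped
      # to the measured allele
      alpha[invalid] <- (centre + stats::rnorm(sum(invalid), 0, sc$pleiotropy_sd)) *
        sign(b_x[invalid])
    } else if (sc$pleiotropy_mode == "outlier") {
      idx <- sample.int(k, sc$n_outlier)
      invalid[idx] <- TRUE
      alpha[idx] <- sc$outlier_multiple * se_y * sign(b_x[idx])
    }

    beta_exp <- b_x + sc$noise_scale * stats::rnorm(k) * se_x
    # guarantee the selection threshold: redraw noise for instruments that
    # miss it (rare given |z| >= 7)
    repeat {
      miss <- two_sided_p(beta_exp / se_x) >= MR_EXPOSURE_P
      if (!any(miss)) break
      beta_exp[miss] <- b_x[miss] + sc$noise_scale * stats::rnorm(sum(miss)) * se_x
      if (sc$noise_scale == 0) break
    }
    beta_out <- sc$beta_causal * b_x + alpha +
      sc$noise_scale * stats::rnorm(k) * se_y

    ids <- sprintf("iv%d", seq_len(k))
    pos <- seq_len(k) * 2e7
    ea <- rep(c("A", "C"), length.out = k)
    oa <- rep(c("G", "T"), length.out = k)
    eaf <- stats::runif(k, 0.15, 0.38)
    if (sc$n_palindromic_intermediate > 0) {
      pal <- seq_len(sc$n_palindromic_intermediate)
      ea[pal] <- "A"; oa[pal] <- "T"; eaf[pal] <- 0.5
    }

    mk <- function(beta, se, n, trait) {
      as_sumstats(data.frame(
        snp_id = ids, chrom = "1", pos = pos,
        effect_allele = ea, other_allele = oa, eaf = eaf,
        beta = beta, se = se, pvalue = floored_p(beta / se), n = n,
        stringsAsFactors = FALSE), trait = trait, n_default = n)
    }
    exposure <- mk(beta_exp, se_x, sc$n1, "exposure")
    outcome <- mk(beta_out, se_y, sc$n2, "outcome")

    if (sc$m_null > 0) {
      nid <- sprintf("null%d", seq_len(sc$m_null))
      npos <- 1e9 + seq_len(sc$m_null) * 1e4
      nea <- rep(c("A", "C"), length.out = sc$m_null)
      noa <- rep(c("G", "T"), length.out = sc$m_null)
      neaf <- stats::runif(sc$m_null, 0.15, 0.38)
      addnull <- function(ss, se, n) {
        z <- stats::rnorm(sc$m_null)
        extra <- data.frame(
          snp_id = nid, chrom = "2", pos = npos,
          effect_allele = nea, other_allele = noa, eaf = neaf,
          beta = z * se, se = se, pvalue = floored_p(z), n = n,
          stringsAsFactors = FALSE)
        as_sumstats(rbind(ss$records, extra), trait = ss$trait, n_default = n)
      }
      exposure <- addnull(exposure, se_x, sc$n1)
      outcome <- addnull(outcome, se_y, sc$n2)
    }

    list(exposure = exposure, outcome = outcome,
         truth = list(beta_causal = sc$beta_causal, snp_id = ids,
                      b_x = b_x, alpha = alpha, invalid = ids[invalid],
                      outliers = if (sc$pleiotropy_mode == "outlier")
                        ids[alpha != 0] else character(0)))
  })
}

#' Write an MR scenario truth record as flat key-value text
#' @param truth Truth record from [simulate_mr_scenario()].
#' @param path Output path.
#' @export
write_truth_record <- function(truth, path) {
  lines <- c(
    sprintf("beta_causal\t%.17g", truth$beta_causal),
    sprintf("outliers\t%s", paste(truth$outliers, collapse = ",")),
    sprintf("invalid\t%s", paste(truth$invalid, collapse = ",")),
    sprintf("%s\tb_x=%.17g\talpha=%.17g", truth$snp_id, truth$b_x, truth$alpha))
  writeLines(lines, path)
  invisible(path)
}

#' Screen-battery configuration
#'
#' Defines the synthetic multi-exposure study used to exercise the full
#' two-stage pipeline: several exposures screened against one outcome by
#' genetic correlation, with a single planted exposure that is both
#' genetically correlated with the outcome and causally upstream of it
#' through planted instruments.
#'
#' Default scales emulate a microbiome-GWAS-sized exposure cohort
#' (N = 2,000) against a larger case-control outcome cohort (N = 5,000
#' effective) over 5,000 desk-scale variants with modest LD-score spread,
#' so mean association chi-square statistics stay in a realistic range
#' (about 1.4) while the planted genetic correlation of -0.6 remains
#' detectable.
#'
#' @param n_exposures Number of exposures screened.
#' @param signal_index Which exposure carries the planted signal.
#' @param m Variant count shared by all studies.
#' @param h2_exp,h2_out Heritabilities of exposures and outcome.
#' @param rg_signal Genetic correlation between the planted exposure and
#'   the outcome (others are 0).
#' @param beta_causal Causal effect of the planted exposure on the
#'   outcome, realised through `k_iv` planted instruments.
#' @param k_iv Number of planted instruments.
#' @param n_exp,n_out GWAS sample sizes.
#' @param l_range LD-score range for the polygenic background.
#' @param seed Integer seed.
#' @export
screen_battery_config <- function(n_exposures = 5, signal_index = 1,
                                  m = 5000, h2_exp = 0.3, h2_out = 0.4,
                                  rg_signal = -0.6, beta_causal = -0.3,
                                  k_iv = 15, n_exp = 2000, n_out = 5000,
                                  l_range = c(1, 4), seed = 1) {
  structure(list(n_exposures = n_exposures, signal_index = signal_index,
                 m = m, h2_exp = h2_exp, h2_out = h2_out,
                 rg_signal = rg_signal, beta_causal = beta_causal,
                 k_iv = k_iv, n_exp = n_exp, n_out = n_out,
                 l_range = l_range, seed = seed),
            class = "screen_battery_config")
}

#' Simulate a multi-exposure screening battery with one planted signal
#'
#' Builds `n_exposures` exposure studies and one outcome study over a
#' shared variant space. The planted exposure shares polygenic signal
#' with the outcome at genetic correlation `rg_signal`; the others are
#' genetically independent of it. `k_iv` additional large-effect
#' instruments (exposure p < 1e-5 by construction) are appended whose
#' outcome effects equal `beta_causal` times their exposure effects plus
#' sampling noise; null exposures carry only noise at those variants. A
#' small independent reference panel covering the instruments supports
#' clumping.
#'
#' @param cfg A [screen_battery_config()].
#' @return List with `outcome`, `exposures` (named list of `sumstats`),
#'   `scores`, `panel` and `truth`.
#' @export
simulate_screen_battery <- function(cfg) {
  stopifnot(inherits(cfg, "screen_battery_config"))
  scores <- synthetic_ld_scores(cfg$m, cfg$l_range,
                                seed = derive_seed(cfg$seed, 1))
  with_seed(derive_seed(cfg$seed, 2), {
    m <- cfg$m
    l <- scores$L2
    # outcome + signal exposure jointly; null exposures independently
    gcfg <- bivariate_gwas_config(h2_1 = cfg$h2_exp, h2_2 = cfg$h2_out,
                                  rg_true = cfg$rg_signal, n1 = cfg$n_exp,
                                  n2 = cfg$n_out, seed = 0)
    z_pair <- draw_bivariate_z(l, m, gcfg)
    z_exp <- matrix(NA_real_, m, cfg$n_exposures)
    z_exp[, cfg$signal_index] <- z_pair[, 1]
    z_out <- z_pair[, 2]
    for (e in setdiff(seq_len(cfg$n_exposures), cfg$signal_index)) {
      v <- cfg$n_exp * cfg$h2_exp * l / m + 1
      z_exp[, e] <- sqrt(v) * stats::rnorm(m)
    }

    # planted instruments appended after the polygenic background
    k <- cfg$k_iv
    se_x <- 1 / sqrt(cfg$n_exp)
    se_y <- 1 / sqrt(cfg$n_out)
    b_x <- (stats::runif(k, 7, 10) / sqrt(cfg$n_exp)) * sample(c(-1, 1), k, TRUE)
    beta_exp_iv <- b_x + stats::rnorm(k) * se_x
    repeat {
      miss <- two_sided_p(beta_exp_iv / se_x) >= MR_EXPOSURE_P
      if (!any(miss)) break
      beta_exp_iv[miss] <- b_x[miss] + stats::rnorm(sum(miss)) * se_x
    }
    beta_out_iv <- cfg$beta_causal * b_x + stats::rnorm(k) * se_y

    iv_ids <- sprintf("iv%d", seq_len(k))
    iv_pos <- seq_len(k) * 2e7
    all_ids <- c(scores$snp_id, iv_ids)
    all_chrom <- c(scores$chrom, rep("2", k))
    all_pos <- c(scores$pos, iv_pos)
    ea <- rep(c("A", "C"), length.out = m + k)
    oa <- rep(c("G", "T"), length.out = m + k)
    eaf <- stats::runif(m + k, 0.15, 0.38)

    mk_ss <- function(beta, se, n, trait) {
      as_sumstats(data.frame(
        snp_id = all_ids, chrom = all_chrom, pos = all_pos,
        effect_allele = ea, other_allele = oa, eaf = eaf,
        beta = beta, se = se, pvalue = floored_p(beta / se), n = n,
        stringsAsFactors = FALSE), trait = trait, n_default = n)
    }

    exposures <- vector("list", cfg$n_exposures)
    names(exposures) <- sprintf("exposure%d", seq_len(cfg$n_exposures))
    for (e in seq_len(cfg$n_exposures)) {
      iv_part <- if (e == cfg$signal_index) beta_exp_iv else
        stats::rnorm(k) * se_x
      exposures[[e]] <- mk_ss(c(z_exp[, e] * se_x, iv_part), se_x,
                              cfg$n_exp, names(exposures)[e])
    }
    outcome <- mk_ss(c(z_out * se_y, beta_out_iv), se_y, cfg$n_out, "outcome")

    # the correlation screen runs on the scored polygenic background only
    # (mirroring real analyses, which restrict the regression to a
    # well-behaved reference variant panel and so exclude large-effect
    # loci); the planted instruments are deliberately left unscored and
    # enter the MR stage only
    scores_all <- scores

    panel <- simulate_panel(panel_config(
      n_ind = 200, m_snps = k, block_size = 1, within_block_r = 0,
      maf_range = c(0.15, 0.38), seed = derive_seed(cfg$seed, 3)))
    panel$geno <- matrix(panel$geno, nrow(panel$geno), k,
                         dimnames = list(NULL, iv_ids))
    panel$variants$snp_id <- iv_ids
    panel$variants$chrom <- "2"
    panel$variants$pos <- iv_pos

    list(outcome = outcome, exposures = exposures, scores = scores_all,
         panel = panel,
         truth = list(signal = names(exposures)[cfg$signal_index],
                      rg_signal = cfg$rg_signal,
                      beta_causal = cfg$beta_causal, iv_ids = iv_ids))
  })
}
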