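# LD score regression: heritability, confounding intercept, genetic
# covariance and genetic correlation, with block-jackknife uncertainty.
#
# Model: for variant j with LD score l_j,
#   E[chi2_j]   = N h2 l_j / M + N a + 1         (single trait)
#   E[z1j z2j]  = sqrt(N1 N2) gencov l_j / M + c (cross trait)
# so the slope of a weighted regression of chi2 (or z-score products) on
# l estimates h2 (or genetic covariance) after rescaling by M/N, and the
# single-trait intercept minus one measures mean confounding inflation.

#' Block-jackknife standard error of an arbitrary statistic
#'
#' Splits the rows of `data` into `n_blocks` contiguous blocks, evaluates
#' `statistic` with each block deleted in turn, and returns the
#' delete-one-block jackknife standard error
#' `sqrt((g - 1)/g * sum((theta_(-i) - mean)^2))`.
#'
#' Contiguous (rather than random) blocks are the appropriate resampling
#' unit for genomic data, where nearby variants are correlated through LD.
#'
#' @param statistic Function of a data subset returning a scalar.
#' @param data Vector, matrix or data.frame; blocks are formed over
#'   elements (vector) or rows.
#' @param n_blocks Number of contiguous blocks (>= 2, <= rows).
#' @return Standard error (scalar).
#' @export
block_jackknife_se <- function(statistic, data, n_blocks) {
  n <- if (is.null(dim(data))) length(data) else nrow(data)
  if (n_blocks < 2) stop("n_blocks must be >= 2", call. = FALSE)
  if (n_blocks > n) stop("fewer observations than jackknife blocks", call. = FALSE)
  grp <- jackknife_groups(n, n_blocks)
  theta <- vapply(seq_len(n_blocks), function(b) {
    keep <- grp != b
    sub <- if (is.null(dim(data))) data[keep] else data[keep, , drop = FALSE]
    statistic(sub)
  }, numeric(1))
  sqrt((n_blocks - 1) / n_blocks * sum((theta - mean(theta))^2))
}

# Contiguous near-equal block assignment of n items into g groups.
jackknife_groups <- function(n, g) {
  sizes <- rep(n %/% g, g) + c(rep(1L, n %% g), rep(0L, g - n %% g))
  rep(seq_len(g), times = sizes)
}

# Default number of jackknife blocks, shrunk for small data.
default_n_blocks <- function(n_snps, n_blocks = 200) {
  max(2L, min(n_blocks, n_snps %/% 50L, n_snps))
}

# Per-block sufficient statistics for weighted regressions of several
# responses on a shared predictor, enabling O(m + g) delete-block fits.
# ys: matrix (m x q). Returns list(total = named totals, blocks = g x
# (5 + q) matrix of block sums).
block_regression_sums <- function(x, ys, w, grp, g) {
  base <- cbind(w, w * x, w * x * x)
  wy <- ys * w
  wxy <- ys * (w * x)
  all <- cbind(base, wy, wxy)
  blocks <- rowsum(all, grp, reorder = TRUE)
  list(total = colSums(all), blocks = blocks, q = ncol(ys))
}

# Delete-block slope and intercept for response column j (1-based among q).
delete_block_line <- function(sums, j) {
  tot <- sums$total
  blk <- sums$blocks
  q <- sums$q
  sw <- tot[1] - blk[, 1]
  swx <- tot[2] - blk[, 2]
  swxx <- tot[3] - blk[, 3]
  swy <- tot[3 + j] - blk[, 3 + j]
  swxy <- tot[3 + q + j] - blk[, 3 + q + j]
  d <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / d
  intercept <- (swy - slope * swx) / sw
  list(slope = slope, intercept = intercept)
}

jackknife_se_from_values <- function(theta) {
  g <- length(theta)
  sqrt((g - 1) / g * sum((theta - mean(theta))^2))
}

# Merge a sumstats object with LD scores, preserving score order.
merge_with_scores <- function(records, scores) {
  idx <- match(scores$snp_id, records$snp_id)
  keep <- !is.na(idx) & !is.na(scores$L2)
  list(records = records[idx[keep], , drop = FALSE],
       l = scores$L2[keep])
}

#' Estimate SNP heritability and confounding intercept
#'
#' Regresses per-variant association chi-square statistics
#' (`(beta/se)^2`) on LD scores by weighted least squares (baseline
#' weights `1/max(l, 1)` as a heteroskedasticity proxy) and rescales the
#' slope by `M/N` to the heritability scale. The intercept is left free:
#' its excess over 1 estimates mean confounding inflation (`N a`).
#' Standard errors come from a delete-one-block jackknife over contiguous
#' variant blocks.
#'
#' @param ss A `sumstats` object.
#' @param scores An `ld_scores` data.frame covering the variants.
#' @param m_total Total variant count `M` in the model denominator;
#'   defaults to the number of merged variants.
#' @param n Sample size `N`; defaults to the mean per-variant `n`.
#' @param n_blocks Jackknife blocks (default 200, shrunk to
#'   `floor(n_snps/50)` for small data).
#' @param chi2_cap Optional chi-square cap: variants exceeding it are
#'   excluded (`NULL`, the default, disables; `TRUE` uses
#'   `max(80, 0.001 N)`).
#' @return An `ldsc_fit` with `h2`, `intercept`, `se_h2`, `se_intercept`,
#'   `n_snps`, `n_blocks`, and fit metadata.
#' @export
estimate_h2 <- function(ss, scores, m_total = NULL, n = NULL,
                        n_blocks = 200, chi2_cap = NULL) {
  stopifnot(inherits(ss, "sumstats"))
  mg <- merge_with_scores(ss$records, scores)
  z <- mg$records$beta / mg$records$se
  chi2 <- z^2
  l <- mg$l
  n <- n %||% mean(mg$records$n, na.rm = TRUE)
  if (!is.finite(n)) stop("sample size n unavailable", call. = FALSE)
  trimmed <- 0L
  cap <- NULL
  if (!is.null(chi2_cap) && !identical(chi2_cap, FALSE)) {
    cap <- if (isTRUE(chi2_cap)) max(80, 0.001 * n) else chi2_cap
    keep <- chi2 <= cap
    trimmed <- sum(!keep)
    chi2 <- chi2[keep]; l <- l[keep]
  }
  m <- length(l)
  if (length(unique(l)) < 2) {
    stop("rank-deficiency error: all LD scores identical", call. = FALSE)
  }
  m_total <- m_total %||% m
  w <- 1 / pmax(l, 1)
  fit <- wls_line(l, chi2, w)
  h2 <- fit$slope * m_total / n

  g <- default_n_blocks(m, n_blocks)
  grp <- jackknife_groups(m, g)
  sums <- block_regression_sums(l, cbind(chi2), w, grp, g)
  del <- delete_block_line(sums, 1)
  se_h2 <- jackknife_se_from_values(del$slope * m_total / n)
  se_int <- jackknife_se_from_values(del$intercept)

  structure(list(h2 = h2, intercept = fit$intercept,
                 se_h2 = se_h2, se_intercept = se_int,
                 n_snps = m, n_blocks = g, n = n, m_total = m_total,
                 weights = "1/max(l,1)", chi2_cap = cap, trimmed = trimmed),
            class = "ldsc_fit")
}

#' @export
print.ldsc_fit <- function(x, ...) {
  cat(sprintf("<ldsc_fit> h2 = %.4f (SE %.4f), intercept = %.4f (SE %.4f), %d variants, %d blocks\n",
              x$h2, x$se_h2, x$intercept, x$se_intercept, x$n_snps, x$n_blocks))
  if (x$trimmed > 0) cat(sprintf(" chi2 cap %.1f trimmed %d variants\n",
                                 x$chi2_cap, x$trimmed))
  invisible(x)
}

#' Estimate cross-trait genetic correlation
#'
#' Harmonizes the two studies onto a common effect-allele frame, then
#' regresses the per-variant z-score product on LD scores; the slope
#' rescaled by `M/sqrt(N1 N2)` estimates genetic covariance, which is
#' normalized by the geometric mean of the two fitted heritabilities to
#' give the genetic correlation. The standard error jackknifes the full
#' ratio statistic (both component heritabilities and the covariance are
#' re-fitted in every delete-block replicate), and
#' `p = 2 pnorm(-|rg|/se)`.
#'
#' @param ss1,ss2 `sumstats` objects.
#' @param scores LD scores covering the shared variants.
#' @param m_total Model denominator `M` (defaults to merged count).
#' @param n1,n2 Sample sizes (default: mean per-variant `n`).
#' @param n_blocks Jackknife blocks.
#' @param chi2_cap Optional chi-square cap applied to both traits (see
#'   [estimate_h2()]).
#' @return An `rg_estimate` with `rg`, `se`, `p`, `gencov`, component
#'   fits `h2_1`, `h2_2`, intercepts, `cross_intercept`, `n_snps`,
#'   `n_blocks`, and `flag` (`"out_of_range"` when `|rg| > 1.25`).
#'   Throws an error when either fitted component heritability is
#'   non-positive (the correlation is then undefined).
#' @export
estimate_rg <- function(ss1, ss2, scores, m_total = NULL, n1 = NULL,
                        n2 = NULL, n_blocks = 200, chi2_cap = NULL) {
  stopifnot(inherits(ss1, "sumstats"), inherits(ss2, "sumstats"))
  hp <- harmonize_pair(ss1, ss2)
  pr <- hp$pairs
  idx <- match(scores$snp_id, pr$snp_id)
  keep <- !is.na(idx) & !is.na(scores$L2)
  pr <- pr[idx[keep], , drop = FALSE]
  l <- scores$L2[keep]
  m <- nrow(pr)
  if (length(unique(l)) < 2) {
    stop("rank-deficiency error: all LD scores identical", call. = FALSE)
  }
  z1 <- pr$beta_exp / pr$se_exp
  z2 <- pr$beta_out / pr$se_out
  n1 <- n1 %||% mean(ss1$records$n, na.rm = TRUE)
  n2 <- n2 %||% mean(ss2$records$n, na.rm = TRUE)
  if (!is.null(chi2_cap) && !identical(chi2_cap, FALSE)) {
    cap1 <- if (isTRUE(chi2_cap)) max(80, 0.001 * n1) else chi2_cap
    cap2 <- if (isTRUE(chi2_cap)) max(80, 0.001 * n2) else chi2_cap
    keep2 <- z1^2 <= cap1 & z2^2 <= cap2
    z1 <- z1[keep2]; z2 <- z2[keep2]; l <- l[keep2]
    m <- length(l)
  }
  m_total <- m_total %||% m
  w <- 1 / pmax(l, 1)

  fit1 <- wls_line(l, z1^2, w)
  fit2 <- wls_line(l, z2^2, w)
  fit12 <- wls_line(l, z1 * z2, w)
  h2_1 <- fit1$slope * m_total / n1
  h2_2 <- fit2$slope * m_total / n2
  if (h2_1 <= 0 || h2_2 <= 0) {
    stop("undefined-rg error: non-positive fitted component heritability (",
         sprintf("h2_1 = %.4g, h2_2 = %.4g", h2_1, h2_2), ")", call. = FALSE)
  }
  gencov <- fit12$slope * m_total / sqrt(n1 * n2)
  rg <- gencov / sqrt(h2_1 * h2_2)

  g <- default_n_blocks(m, n_blocks)
  grp <- jackknife_groups(m, g)
  sums <- block_regression_sums(l, cbind(z1^2, z2^2, z1 * z2), w, grp, g)
  d1 <- delete_block_line(sums, 1)
  d2 <- delete_block_line(sums, 2)
  d12 <- delete_block_line(sums, 3)
  h2_1_del <- d1$slope * m_total / n1
  h2_2_del <- d2$slope * m_total / n2
  gencov_del <- d12$slope * m_total / sqrt(n1 * n2)
  rg_del <- gencov_del / sqrt(pmax(h2_1_del, 1e-12) * pmax(h2_2_del, 1e-12))
  se_rg <- jackknife_se_from_values(rg_del)
  p <- if (se_rg > 0) two_sided_p(rg / se_rg) else NA_real_

  structure(list(rg = rg, se = se_rg, p = p, gencov = gencov,
                 h2_1 = h2_1, h2_2 = h2_2,
                 intercept_1 = fit1$intercept, intercept_2 = fit2$intercept,
                 cross_intercept = fit12$intercept,
                 n_snps = m, n_blocks = g, n1 = n1, n2 = n2,
                 m_total = m_total, weights = "1/max(l,1)",
                 flag = if (abs(rg) > 1.25) "out_of_range" else ""),
            class = "rg_estimate")
}

#' @export
print.rg_estimate <- function(x, ...) {
  cat(sprintf("<rg_estimate> rg = %.4f (SE %.4f, p = %.3g), gencov = %.4g, h2 = %.3f/%.3f, %d variants\n",
              x$rg, x$se, x$p, x$gencov, x$h2_1, x$h2_2, x$n_snps))
  if (nzchar(x$flag)) cat(" flag:", x$flag, "\n")
  invisible(x)
}

#' Serialize genetic-correlation estimates as a flat table
#'
#' One row per trait pair with columns `trait1`, `trait2`, `rg`, `se`,
#' `p`, `h2_1`, `h2_2`, `intercept1`, `intercept2`, `n_snps`, `n_blocks`.
#'
#' @param fits Named list of `rg_estimate` objects (names
#'   `"trait1|trait2"` or arbitrary labels used as `trait1`).
#' @param trait2 Outcome label used for all rows.
#' @param path Optional output path (tab-separated).
#' @return The table, invisibly when written.
#' @export
rg_table <- function(fits, trait2 = "outcome", path = NULL) {
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(trait1 = nm, trait2 = trait2, rg = f$rg, se = f$se, p = f$p,
               h2_1 = f$h2_1, h2_2 = f$h2_2,
               intercept1 = f$intercept_1, intercept2 = f$intercept_2,
               n_snps = f$n_snps, n_blocks = f$n_blocks,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
    return(invisible(out))
  }
  out
}
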