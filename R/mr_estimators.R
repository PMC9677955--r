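# Two-sample Mendelian randomization estimators over a harmonized
# instrument set: random-effects inverse-variance weighted (the primary
# method), Egger regression, weighted median, and the simple / weighted
# mode estimators.
#
# All five share the per-instrument Wald ratio kernel
#   ratio_j = beta_out_j / beta_exp_j,  se_j = se_out_j / |beta_exp_j|
# (first-order delta method). P-values are two-sided normal; median and
# mode standard errors come from a parametric bootstrap.

# Accept an iv_set, harmonized_pair, or bare data.frame with the
# required columns.
as_iv_table <- function(iv) {
  tab <- if (inherits(iv, "iv_set")) iv$instruments
  else if (inherits(iv, "harmonized_pair")) iv$pairs
  else as.data.frame(iv, stringsAsFactors = FALSE)
  need <- c("beta_exp", "se_exp", "beta_out", "se_out")
  if (!all(need %in% names(tab))) {
    stop("instrument table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (is.null(tab$snp_id)) tab$snp_id <- sprintf("snp%d", seq_len(nrow(tab)))
  tab
}

new_mr_result <- function(method, k, beta, se, extra = list()) {
  z <- beta / se
  ci <- beta + stats::qnorm(c(0.025, 0.975)) * se
  structure(list(method = method, k = k, beta = beta, se = se,
                 pvalue = two_sided_p(z), or = exp(beta),
                 ci_low = exp(ci[1]), ci_high = exp(ci[2]),
                 extra = extra), class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("<mr_result> %s: beta = %.4f (SE %.4f), p = %.3g, OR = %.4f [%.4f, %.4f], k = %d\n",
              x$method, x$beta, x$se, x$pvalue, x$or, x$ci_low, x$ci_high, x$k))
  invisible(x)
}

#' Per-instrument Wald ratio estimates
#'
#' `ratio = beta_out / beta_exp` with first-order standard error
#' `se_out / |beta_exp|` (exposure-effect uncertainty ignored; the
#' second-order correction adding `beta_out^2 se_exp^2 / beta_exp^4` is
#' available behind `second_order`). Instruments with a zero exposure
#' effect have no defined ratio and are excluded with a log entry.
#'
#' @param iv An `iv_set`, `harmonized_pair` or data.frame with columns
#'   `beta_exp`, `se_exp`, `beta_out`, `se_out`.
#' @param second_order Use the second-order delta-method standard error.
#' @return data.frame `snp_id`, `ratio`, `se`, with an `excluded`
#'   attribute listing instruments dropped for zero exposure effect.
#' @export
wald_ratios <- function(iv, second_order = FALSE) {
  tab <- as_iv_table(iv)
  zero <- tab$beta_exp == 0
  excluded <- tab$snp_id[zero]
  tab <- tab[!zero, , drop = FALSE]
  se <- if (second_order) {
    sqrt(tab$se_out^2 / tab$beta_exp^2 +
           tab$beta_out^2 * tab$se_exp^2 / tab$beta_exp^4)
  } else {
    tab$se_out / abs(tab$beta_exp)
  }
  out <- data.frame(snp_id = tab$snp_id,
                    ratio = tab$beta_out / tab$beta_exp,
                    se = se, stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  out
}

#' Random-effects inverse-variance-weighted estimator
#'
#' Inverse-variance-weighted mean of the Wald ratios. Under
#' heterogeneity the multiplicative random-effects convention inflates
#' the fixed-effect standard error by `sqrt(Q/(k-1))` when that exceeds
#' 1; the standard error is never deflated below the fixed-effect value.
#'
#' @param iv Instrument set (see [wald_ratios()]).
#' @return An `mr_result`; `extra` carries `q` (Cochran's Q) and
#'   `inflation` (the applied factor).
#' @export
mr_ivw <- function(iv) {
  wr <- wald_ratios(iv)
  k <- nrow(wr)
  if (k < 2) stop("insufficient-instruments error: IVW needs k >= 2",
                  call. = FALSE)
  w <- 1 / wr$se^2
  beta <- sum(w * wr$ratio) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  q <- sum(w * (wr$ratio - beta)^2)
  inflation <- max(1, sqrt(q / (k - 1)))
  new_mr_result("IVW-RE", k, beta, se_fixed * inflation,
                extra = list(q = q, inflation = inflation,
                             se_fixed = se_fixed))
}

# Shared Egger weighted-regression kernel. Orientation convention: the
# exposure effect of every pair is made non-negative by flipping the
# (beta_exp, beta_out) signs together, so the intercept has a consistent
# meaning. Weights 1/se_out^2; multiplicative overdispersion with floor 1.
egger_fit <- function(iv) {
  tab <- as_iv_table(iv)
  k <- nrow(tab)
  if (k < 3) stop("insufficient-instruments error: Egger needs k >= 3",
                  call. = FALSE)
  flip <- sign(tab$beta_exp)
  flip[flip == 0] <- 1
  x <- tab$beta_exp * flip
  y <- tab$beta_out * flip
  w <- 1 / tab$se_out^2
  fit <- wls_line(x, y, w)
  rss <- sum(w * (y - fit$intercept - fit$slope * x)^2)
  sigma2 <- max(1, rss / (k - 2))
  list(slope = fit$slope, intercept = fit$intercept,
       se_slope = sqrt(sigma2 * fit$var_slope_unit),
       se_intercept = sqrt(sigma2 * fit$var_intercept_unit),
       rss = rss, sigma2 = sigma2, k = k, x = x, y = y, w = w)
}

#' MR-Egger regression
#'
#' Weighted regression of (orientation-standardized) outcome effects on
#' exposure effects with a free intercept. The slope estimates the
#' causal effect under the weaker InSIDE assumption; the intercept
#' estimates average directional pleiotropy and is tested by
#' [egger_intercept_test()].
#'
#' @param iv Instrument set.
#' @return An `mr_result` for the slope; `extra` carries `intercept`,
#'   `se_intercept`, `p_intercept` and the overdispersion `sigma2`.
#' @export
mr_egger <- function(iv) {
  f <- egger_fit(iv)
  new_mr_result("Egger", f$k, f$slope, f$se_slope,
                extra = list(intercept = f$intercept,
                             se_intercept = f$se_intercept,
                             p_intercept = two_sided_p(f$intercept / f$se_intercept),
                             sigma2 = f$sigma2))
}

# Weighted 50th percentile of sorted values with linear interpolation
# across the cumulative-weight 0.5 boundary.
weighted_median_value <- function(x, w) {
  o <- order(x)
  x <- x[o]
  w <- w[o]
  cw <- (cumsum(w) - 0.5 * w) / sum(w)
  if (cw[1] >= 0.5) return(x[1])
  n <- length(x)
  if (cw[n] <= 0.5) return(x[n])
  below <- max(which(cw < 0.5))
  x[below] + (x[below + 1] - x[below]) *
    (0.5 - cw[below]) / (cw[below + 1] - cw[below])
}

# Parametric bootstrap over instrument effect estimates; returns the sd
# of the re-computed estimator.
bootstrap_se <- function(tab, estimator, n_boot, seed) {
  with_seed(seed, {
    k <- nrow(tab)
    est <- vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(k, tab$beta_exp, tab$se_exp)
      by <- stats::rnorm(k, tab$beta_out, tab$se_out)
      bx[bx == 0] <- .Machine$double.eps
      estimator(by / bx, tab$se_out / abs(bx))
    }, numeric(1))
    stats::sd(est)
  })
}

#' Weighted-median estimator
#'
#' Weighted 50th percentile of the Wald ratios with inverse-variance
#' weights, consistent when at least half the total weight comes from
#' valid instruments. The standard error is a parametric bootstrap over
#' per-instrument effect estimates.
#'
#' @param iv Instrument set.
#' @param n_boot Bootstrap resamples.
#' @param seed RNG seed for the bootstrap.
#' @return An `mr_result`.
#' @export
mr_weighted_median <- function(iv, n_boot = 1000, seed = 1) {
  tab <- as_iv_table(iv)
  tab <- tab[tab$beta_exp != 0, , drop = FALSE]
  k <- nrow(tab)
  if (k < 3) stop("insufficient-instruments error: weighted median needs k >= 3",
                  call. = FALSE)
  wr <- wald_ratios(tab)
  beta <- weighted_median_value(wr$ratio, 1 / wr$se^2)
  se <- bootstrap_se(tab, function(r, s) weighted_median_value(r, 1 / s^2),
                     n_boot, seed)
  new_mr_result("weighted-median", k, beta, se)
}

# Weighted Gaussian kernel-density mode of x. Bandwidth: a median-
# absolute-deviation Silverman-style rule scaled by bandwidth_factor.
kde_mode <- function(x, w, bandwidth_factor = 1) {
  if (length(unique(x)) == 1) return(x[1])
  s <- stats::mad(x)
  if (s == 0) s <- stats::sd(x)
  h <- bandwidth_factor * 0.9 * s * length(x)^(-1 / 5)
  if (h == 0) return(x[1])
  grid <- seq(min(x) - 3 * h, max(x) + 3 * h, length.out = 512)
  w <- w / sum(w)
  dens <- vapply(grid, function(g) sum(w * stats::dnorm((g - x) / h)),
                 numeric(1))
  grid[which.max(dens)]
}

#' Mode-based estimators (simple and weighted)
#'
#' Kernel-density mode of the Wald ratios: unweighted for the simple
#' mode, inverse-variance weighted for the weighted mode. Consistent
#' when the largest homogeneous cluster of instruments is valid (the
#' ZEMPA assumption). When all ratios coincide the common ratio is
#' returned directly. Standard errors by parametric bootstrap.
#'
#' @param iv Instrument set.
#' @param weighted Use inverse-variance weights.
#' @param bandwidth_factor Multiplier on the median-absolute-deviation
#'   bandwidth rule.
#' @param n_boot Bootstrap resamples.
#' @param seed RNG seed for the bootstrap.
#' @return An `mr_result` (method `"simple-mode"` or `"weighted-mode"`).
#' @export
mr_mode <- function(iv, weighted = FALSE, bandwidth_factor = 1,
                    n_boot = 1000, seed = 1) {
  tab <- as_iv_table(iv)
  tab <- tab[tab$beta_exp != 0, , drop = FALSE]
  k <- nrow(tab)
  if (k < 3) stop("insufficient-instruments error: mode estimators need k >= 3",
                  call. = FALSE)
  wr <- wald_ratios(tab)
  wfun <- if (weighted) function(s) 1 / s^2 else function(s) rep(1, length(s))
  beta <- kde_mode(wr$ratio, wfun(wr$se), bandwidth_factor)
  se <- bootstrap_se(tab, function(r, s) kde_mode(r, wfun(s), bandwidth_factor),
                     n_boot, seed)
  new_mr_result(if (weighted) "weighted-mode" else "simple-mode", k, beta, se)
}

#' Run all five MR estimators
#'
#' @param iv Instrument set.
#' @param n_boot Bootstrap resamples for median/mode standard errors.
#' @param seed Master seed; the three bootstrap-based methods use seeds
#'   derived from it.
#' @return data.frame with one row per method: `method`, `nsnp`, `beta`,
#'   `se`, `pvalue`, `OR`, `CI_low`, `CI_high`.
#' @export
mr_all <- function(iv, n_boot = 1000, seed = 1) {
  res <- list(
    mr_ivw(iv),
    mr_egger(iv),
    mr_weighted_median(iv, n_boot, derive_seed(seed, 1)),
    mr_mode(iv, weighted = FALSE, n_boot = n_boot, seed = derive_seed(seed, 2)),
    mr_mode(iv, weighted = TRUE, n_boot = n_boot, seed = derive_seed(seed, 3)))
  do.call(rbind, lapply(res, function(r) {
    data.frame(method = r$method, nsnp = r$k, beta = r$beta, se = r$se,
               pvalue = r$pvalue, OR = r$or, CI_low = r$ci_low,
               CI_high = r$ci_high, stringsAsFactors = FALSE)
  }))
}

#' Scatter-plot data export
#'
#' Per-instrument effect estimates plus each method's fitted line
#' (slope, and intercept for Egger), for external plotting.
#'
#' @param iv Instrument set.
#' @param results data.frame from [mr_all()] (recomputed when `NULL`).
#' @param n_boot,seed Passed to [mr_all()] when recomputing.
#' @return List with `points` (per-instrument `snp_id`, `beta_exp`,
#'   `se_exp`, `beta_out`, `se_out`) and `lines` (`method`, `slope`,
#'   `intercept`).
#' @export
mr_scatter_data <- function(iv, results = NULL, n_boot = 1000, seed = 1) {
  tab <- as_iv_table(iv)
  if (is.null(results)) results <- mr_all(iv, n_boot, seed)
  egger <- egger_fit(iv)
  lines <- data.frame(method = results$method, slope = results$beta,
                      intercept = ifelse(results$method == "Egger",
                                         egger$intercept, 0),
                      stringsAsFactors = FALSE)
  list(points = tab[, c("snp_id", "beta_exp", "se_exp", "beta_out", "se_out")],
       lines = lines)
}
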