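# Heterogeneity and horizontal-pleiotropy diagnostics: Cochran's Q for
# the IVW fit, Rucker's Q for the Egger fit, the Egger intercept test,
# and a simulation-based residual sum-of-squares battery (global
# pleiotropy test, per-instrument outlier test, and a distortion test
# quantifying the estimate shift after outlier removal).

#' Cochran's Q heterogeneity statistic for the IVW fit
#'
#' `Q = sum_j w_j (ratio_j - beta_ivw)^2` with inverse-variance ratio
#' weights; under instrument homogeneity Q is chi-square with `k - 1`
#' degrees of freedom.
#'
#' @param iv Instrument set.
#' @param ivw_beta IVW estimate to centre on; recomputed when `NULL`.
#' @return List `q`, `df`, `p`.
#' @export
cochran_q <- function(iv, ivw_beta = NULL) {
  wr <- wald_ratios(iv)
  k <- nrow(wr)
  if (k < 2) stop("insufficient-instruments error: Q needs k >= 2",
                  call. = FALSE)
  w <- 1 / wr$se^2
  if (is.null(ivw_beta)) ivw_beta <- sum(w * wr$ratio) / sum(w)
  q <- sum(w * (wr$ratio - ivw_beta)^2)
  list(q = q, df = k - 1L, p = stats::pchisq(q, k - 1, lower.tail = FALSE))
}

#' Rucker's Q heterogeneity statistic for the Egger fit
#'
#' Weighted residual sum of squares around the Egger regression line,
#' chi-square with `k - 2` degrees of freedom under homogeneity. Because
#' the Egger fit adds a free intercept to the (no-intercept) IVW
#' regression, Rucker's Q never exceeds Cochran's Q.
#'
#' @param iv Instrument set.
#' @param fit Optional precomputed internal Egger fit.
#' @return List `q`, `df`, `p`.
#' @export
rucker_q <- function(iv, fit = NULL) {
  f <- fit %||% egger_fit(iv)
  list(q = f$rss, df = f$k - 2L,
       p = stats::pchisq(f$rss, f$k - 2, lower.tail = FALSE))
}

#' Egger intercept test for directional pleiotropy
#'
#' Two-sided test of a zero Egger intercept using the regression
#' standard error with a multiplicative overdispersion floor of 1
#' (matching the IVW random-effects convention). A small p-value
#' indicates average directional pleiotropy across instruments.
#'
#' @param iv Instrument set.
#' @param fit Optional precomputed internal Egger fit.
#' @return List `intercept`, `se`, `p`.
#' @export
egger_intercept_test <- function(iv, fit = NULL) {
  f <- fit %||% egger_fit(iv)
  z <- f$intercept / f$se_intercept
  list(intercept = f$intercept, se = f$se_intercept, p = two_sided_p(z))
}

# Leave-one-out no-intercept IVW slopes for all instruments at once.
# bx, by: effect vectors; w: weights (1/se_out^2).
loo_ivw_slopes <- function(bx, by, w) {
  num <- sum(w * bx * by)
  den <- sum(w * bx * bx)
  (num - w * bx * by) / (den - w * bx * bx)
}

#' Simulation-based pleiotropy residual and outlier battery
#'
#' Implements the canonical three-part residual sum-of-squares test.
#' Global test: the observed weighted RSS of leave-one-out IVW
#' predictions is compared against `n_sim` parametric simulations of the
#' instrument effects under no pleiotropy. Outlier test: each
#' instrument's observed squared residual is compared against its own
#' simulated reference distribution, with Bonferroni correction over the
#' `k` instruments; instruments below `sig_level` are flagged. Distortion
#' test: the relative shift of the IVW estimate after removing flagged
#' outliers is compared against a distribution built by re-estimating on
#' random instrument subsets of the same size as the non-outlier set.
#' When no outlier is flagged the distortion test reports `NA`.
#'
#' @param iv Instrument set (k >= 4 required).
#' @param n_sim Number of parametric simulations.
#' @param seed Master seed for all simulation draws.
#' @param sig_level Significance level for outlier flagging.
#' @return An `mr_presso_result`: list with `global_rss`, `global_p`,
#'   `outlier_table` (`snp_id`, `rss`, `p_bonf`, `flagged`), `outliers`,
#'   `distortion_coef` (percent shift), `distortion_p`, `beta_all`,
#'   `beta_no_outliers`, and the simulation settings.
#' @export
mr_presso <- function(iv, n_sim = 1000, seed = 1, sig_level = 0.05) {
  tab <- as_iv_table(iv)
  tab <- tab[tab$beta_exp != 0, , drop = FALSE]
  k <- nrow(tab)
  if (k < 4) {
    stop("insufficient-instruments error: the residual outlier battery needs k >= 4",
         call. = FALSE)
  }
  bx <- tab$beta_exp
  by <- tab$beta_out
  sx <- tab$se_exp
  sy <- tab$se_out
  w <- 1 / sy^2

  b_loo <- loo_ivw_slopes(bx, by, w)
  obs_res <- w * (by - b_loo * bx)^2
  rss_obs <- sum(obs_res)

  with_seed(seed, {
    # parametric no-pleiotropy reference: instrument effects redrawn
    # around the leave-one-out predictions
    sim_res <- matrix(NA_real_, k, n_sim)
    for (s in seq_len(n_sim)) {
      bxs <- stats::rnorm(k, bx, sx)
      bys <- stats::rnorm(k, b_loo * bx, sy)
      b_loo_s <- loo_ivw_slopes(bxs, bys, w)
      sim_res[, s] <- w * (bys - b_loo_s * bxs)^2
    }
    rss_sim <- colSums(sim_res)
    global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)

    p_out <- vapply(seq_len(k), function(j) {
      (1 + sum(sim_res[j, ] >= obs_res[j])) / (n_sim + 1)
    }, numeric(1))
    p_bonf <- pmin(1, p_out * k)
    flagged <- p_bonf < sig_level
    outlier_table <- data.frame(snp_id = tab$snp_id, rss = obs_res,
                                p_bonf = p_bonf, flagged = flagged,
                                stringsAsFactors = FALSE)

    ivw_slope <- function(idx) {
      sum(w[idx] * bx[idx] * by[idx]) / sum(w[idx] * bx[idx]^2)
    }
    beta_all <- ivw_slope(seq_len(k))
    distortion_coef <- NA_real_
    distortion_p <- NA_real_
    beta_no <- NA_real_
    if (any(flagged) && sum(!flagged) >= 2) {
      keep <- which(!flagged)
      beta_no <- ivw_slope(keep)
      distortion_coef <- 100 * (beta_all - beta_no) / abs(beta_no)
      d_sim <- vapply(seq_len(n_sim), function(s) {
        idx <- sample.int(k, length(keep))
        b_sub <- ivw_slope(idx)
        100 * (beta_all - b_sub) / abs(b_sub)
      }, numeric(1))
      distortion_p <- (1 + sum(abs(d_sim) >= abs(distortion_coef))) /
        (n_sim + 1)
    }

    structure(list(global_rss = rss_obs, global_p = global_p,
                   outlier_table = outlier_table,
                   outliers = tab$snp_id[flagged],
                   distortion_coef = distortion_coef,
                   distortion_p = distortion_p,
                   beta_all = beta_all, beta_no_outliers = beta_no,
                   n_sim = n_sim, seed = seed, sig_level = sig_level),
              class = "mr_presso_result")
  })
}

#' @export
print.mr_presso_result <- function(x, ...) {
  cat(sprintf("<mr_presso_result> global RSS = %.4g, global p = %.4g\n",
              x$global_rss, x$global_p))
  if (length(x$outliers)) {
    cat(sprintf(" outliers: %s; distortion %.1f%% (p = %.4g)\n",
                paste(x$outliers, collapse = ", "),
                x$distortion_coef, x$distortion_p))
  } else {
    cat(" outliers: none (distortion test NA)\n")
  }
  invisible(x)
}

#' Full sensitivity battery for one instrument set
#'
#' Runs Cochran's Q (IVW), Rucker's Q (Egger), the Egger intercept test
#' and the simulation-based residual battery, returning them as one
#' report.
#'
#' @param iv Instrument set.
#' @param n_sim Simulations for the residual battery.
#' @param seed Master seed (recorded in the report).
#' @param sig_level Outlier flagging level.
#' @return A `sensitivity_report` list.
#' @export
sensitivity_report <- function(iv, n_sim = 1000, seed = 1, sig_level = 0.05) {
  f <- egger_fit(iv)
  cq <- cochran_q(iv)
  rq <- rucker_q(iv, f)
  it <- egger_intercept_test(iv, f)
  pr <- mr_presso(iv, n_sim = n_sim, seed = seed, sig_level = sig_level)
  structure(list(
    q_ivw = cq$q, df_ivw = cq$df, p_q_ivw = cq$p,
    q_egger = rq$q, df_egger = rq$df, p_q_egger = rq$p,
    egger_intercept = it$intercept, se_intercept = it$se,
    p_intercept = it$p,
    presso_global_p = pr$global_p,
    presso_outliers = pr$outliers,
    presso_distortion_p = pr$distortion_p,
    presso = pr, seed = seed), class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("<sensitivity_report> Q = %.3f (df %d, p = %.3g); Q' = %.3f (df %d, p = %.3g)\n",
              x$q_ivw, x$df_ivw, x$p_q_ivw, x$q_egger, x$df_egger, x$p_q_egger))
  cat(sprintf(" Egger intercept %.4g (SE %.4g, p = %.3g); global p = %.3g; outliers: %s\n",
              x$egger_intercept, x$se_intercept, x$p_intercept,
              x$presso_global_p,
              if (length(x$presso_outliers)) paste(x$presso_outliers, collapse = ",")
              else "NA"))
  invisible(x)
}

#' Serialize sensitivity reports as a flat table
#'
#' One row per exposure-outcome pair with columns ordered: Cochran's Q
#' p-value, Rucker's Q p-value, Egger intercept p-value, distortion-test
#' outliers (the not-applicable marker `NA` when none are flagged), and
#' the global-test p-value.
#'
#' @param reports Named list of `sensitivity_report` objects (names are
#'   exposure labels).
#' @param outcome Outcome label.
#' @param path Optional output path (tab-separated).
#' @export
sensitivity_table <- function(reports, outcome = "outcome", path = NULL) {
  rows <- lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(exposure = nm, outcome = outcome,
               cochran_q_p = r$p_q_ivw, rucker_q_p = r$p_q_egger,
               egger_intercept_p = r$p_intercept,
               distortion_outliers = if (length(r$presso_outliers))
                 paste(r$presso_outliers, collapse = ",") else "NA",
               global_p = r$presso_global_p,
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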