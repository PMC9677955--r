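# Two-stage screening pipeline: genetic-correlation screen over many
# exposures against one outcome with multiple-testing control, then the
# full MR + sensitivity battery on exposures reaching the suggestive or
# significant tier.

#' Multiple-testing adjustment for a screening pass
#'
#' Returns the Bonferroni threshold `alpha / n_tests` (stored at full
#' precision, with a 2-significant-figure display form) and
#' Benjamini-Hochberg step-up q-values.
#'
#' @param ps Vector of p-values in (0, 1]. `NA` entries (failed tests)
#'   receive `NA` q-values but still count toward the family size: every
#'   screened exposure is a test.
#' @param alpha Family-wise level.
#' @param method FDR method passed to [stats::p.adjust()].
#' @return List `bonferroni` (full precision), `bonferroni_display`
#'   (2 s.f.), `qvalues`.
#' @export
adjust_pvalues <- function(ps, alpha = 0.05, method = "BH") {
  if (length(ps) == 0) stop("no p-values supplied", call. = FALSE)
  bad <- !is.na(ps) & (ps <= 0 | ps > 1)
  if (any(bad)) stop("invalid p-value(s) outside (0, 1]", call. = FALSE)
  thr <- alpha / length(ps)
  q <- stats::p.adjust(ps, method = method, n = length(ps))
  list(bonferroni = thr, bonferroni_display = signif(thr, 2), qvalues = q)
}

#' Screening configuration
#'
#' @param alpha Suggestive-association level (upper end of the
#'   suggestive band); the Bonferroni threshold `alpha / n_exposures` is
#'   computed at run time.
#' @param fdr_method FDR method for the q-value column.
#' @param mr_tiers Tiers that trigger the MR + sensitivity battery.
#' @param n_blocks Jackknife blocks for the correlation fits.
#' @param mr_n_boot Bootstrap resamples for median/mode standard errors.
#' @param presso_n_sim Simulations for the residual pleiotropy battery.
#' @param sig_level Outlier flagging level.
#' @param iv An [iv_config()].
#' @param seed Master seed; all per-exposure randomness derives from it.
#' @export
screen_config <- function(alpha = 0.05, fdr_method = "BH",
                          mr_tiers = c("significant", "suggestive"),
                          n_blocks = 200, mr_n_boot = 1000,
                          presso_n_sim = 1000, sig_level = 0.05,
                          iv = iv_config(), seed = 1) {
  structure(list(alpha = alpha, fdr_method = fdr_method,
                 mr_tiers = mr_tiers, n_blocks = n_blocks,
                 mr_n_boot = mr_n_boot, presso_n_sim = presso_n_sim,
                 sig_level = sig_level, iv = iv, seed = seed),
            class = "screen_config")
}

#' Run the two-stage screen
#'
#' Stage 1 estimates the genetic correlation of every exposure with the
#' outcome and assigns tiers: `significant` (p <= alpha/n),
#' `suggestive` (alpha/n < p <= alpha), `null` otherwise. A
#' Benjamini-Hochberg q-value column accompanies the raw p-values.
#' Stage 2 runs instrument selection, all five MR estimators and the
#' full sensitivity battery on every exposure in a triggering tier.
#' Per-exposure failures (e.g. a non-positive fitted heritability, or no
#' instrument surviving selection) are recorded in the report and never
#' abort the remaining exposures.
#'
#' @param outcome `sumstats` of the outcome trait.
#' @param exposures Named list of `sumstats` (names become trait labels;
#'   unnamed lists use each object's `trait`).
#' @param scores LD scores shared by all studies.
#' @param panel Reference panel for clumping/proxy search (may be
#'   `NULL`).
#' @param cfg A [screen_config()].
#' @return A `screen_report`: list with `screen` (data.frame `trait`,
#'   `rg`, `se`, `p`, `fdr`, `tier`, `reason`), `mr` and `sensitivity`
#'   (named lists for triggered exposures), `iv` (instrument sets),
#'   `scatter`, and `manifest`.
#' @export
run_screen <- function(outcome, exposures, scores, panel = NULL,
                       cfg = screen_config()) {
  stopifnot(inherits(outcome, "sumstats"))
  n_exp <- length(exposures)
  labels <- names(exposures) %||% vapply(exposures, function(e) e$trait, "")
  if (is.null(names(exposures)) || any(names(exposures) == "")) {
    labels <- vapply(exposures, function(e) e$trait, "")
  }
  if (n_exp == 0) {
    warning("empty exposure list: nothing to screen")
    return(structure(list(
      screen = data.frame(trait = character(0), rg = numeric(0),
                          se = numeric(0), p = numeric(0), fdr = numeric(0),
                          tier = character(0), reason = character(0),
                          stringsAsFactors = FALSE),
      mr = list(), sensitivity = list(), iv = list(), scatter = list(),
      manifest = screen_manifest(cfg, 0)), class = "screen_report"))
  }

  rg <- se <- p <- rep(NA_real_, n_exp)
  reason <- rep("", n_exp)
  for (i in seq_len(n_exp)) {
    fit <- tryCatch(
      estimate_rg(exposures[[i]], outcome, scores, n_blocks = cfg$n_blocks),
      error = function(e) e)
    if (inherits(fit, "error")) {
      reason[i] <- conditionMessage(fit)
    } else {
      rg[i] <- fit$rg; se[i] <- fit$se; p[i] <- fit$p
      if (nzchar(fit$flag)) reason[i] <- fit$flag
    }
  }

  adj <- adjust_pvalues(p, alpha = cfg$alpha, method = cfg$fdr_method)
  tier <- ifelse(is.na(p), "null",
                 ifelse(p <= adj$bonferroni, "significant",
                        ifelse(p <= cfg$alpha, "suggestive", "null")))

  mr <- list(); sens <- list(); ivs <- list(); scatter <- list()
  for (i in which(tier %in% cfg$mr_tiers)) {
    lab <- labels[i]
    sd_i <- derive_seed(cfg$seed, i)
    res <- tryCatch({
      iv <- select_instruments(exposures[[i]], outcome, panel, cfg$iv)
      mr_tab <- mr_all(iv, n_boot = cfg$mr_n_boot, seed = sd_i)
      sr <- sensitivity_report(iv, n_sim = cfg$presso_n_sim,
                               seed = derive_seed(sd_i, 99),
                               sig_level = cfg$sig_level)
      list(iv = iv, mr = mr_tab, sens = sr,
           scatter = mr_scatter_data(iv, mr_tab))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      reason[i] <- paste0("mr_failed: ", conditionMessage(res))
    } else {
      ivs[[lab]] <- res$iv
      mr[[lab]] <- res$mr
      sens[[lab]] <- res$sens
      scatter[[lab]] <- res$scatter
    }
  }

  screen <- data.frame(trait = labels, rg = rg, se = se, p = p,
                       fdr = adj$qvalues, tier = tier, reason = reason,
                       stringsAsFactors = FALSE)
  structure(list(screen = screen, mr = mr, sensitivity = sens, iv = ivs,
                 scatter = scatter,
                 manifest = screen_manifest(cfg, n_exp)),
            class = "screen_report")
}

# Flat key-value manifest sufficient to reconstruct the configuration.
screen_manifest <- function(cfg, n_exposures) {
  c(alpha = cfg$alpha, fdr_method = cfg$fdr_method,
    bonferroni = if (n_exposures > 0) cfg$alpha / n_exposures else NA,
    mr_tiers = paste(cfg$mr_tiers, collapse = ","),
    n_blocks = cfg$n_blocks, mr_n_boot = cfg$mr_n_boot,
    presso_n_sim = cfg$presso_n_sim, sig_level = cfg$sig_level,
    p_exposure_max = cfg$iv$p_exposure_max, clump_r2 = cfg$iv$clump_r2,
    clump_kb = cfg$iv$clump_kb, p_outcome_max = cfg$iv$p_outcome_max,
    proxy_r2_min = cfg$iv$proxy_r2_min,
    palindrome_band = paste(cfg$iv$palindrome_band, collapse = ","),
    confounder_snps = paste(cfg$iv$confounder_snps, collapse = ","),
    seed = cfg$seed, n_exposures = n_exposures,
    package_version = as.character(utils::packageVersion("ldscmr")))
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("<screen_report> %d exposures: %d significant, %d suggestive, %d null\n",
              nrow(x$screen), sum(x$screen$tier == "significant"),
              sum(x$screen$tier == "suggestive"),
              sum(x$screen$tier == "null")))
  invisible(x)
}

#' Write a screen report to a directory of tab-separated tables
#'
#' Writes `screen.tsv` (trait, rg, se, p, fdr, tier, reason), `mr.tsv`
#' (stacked five-method blocks per triggered exposure),
#' `sensitivity.tsv`, `scatter.tsv` (per-instrument points and fitted
#' lines) and `manifest.txt` (flat key-value configuration echo). Output
#' is deterministic for identical inputs, configuration and master seed.
#'
#' @param report A `screen_report`.
#' @param dir Output directory (created if absent).
#' @param outcome Outcome label for the sensitivity table.
#' @return `dir`, invisibly.
#' @export
write_screen_report <- function(report, dir, outcome = "outcome") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(report$screen, file.path(dir, "screen.tsv"),
                     sep = "\t", na = "NA", quote = FALSE)
  if (length(report$mr) > 0) {
    mr <- do.call(rbind, lapply(names(report$mr), function(nm) {
      cbind(exposure = nm, report$mr[[nm]], stringsAsFactors = FALSE)
    }))
    data.table::fwrite(mr, file.path(dir, "mr.tsv"), sep = "\t",
                       na = "NA", quote = FALSE)
    sensitivity_table(report$sensitivity, outcome = outcome,
                      path = file.path(dir, "sensitivity.tsv"))
    pts <- do.call(rbind, lapply(names(report$scatter), function(nm) {
      cbind(exposure = nm, report$scatter[[nm]]$points,
            stringsAsFactors = FALSE)
    }))
    data.table::fwrite(pts, file.path(dir, "scatter.tsv"), sep = "\t",
                       na = "NA", quote = FALSE)
  }
  writeLines(sprintf("%s\t%s", names(report$manifest), report$manifest),
             file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' Read a manifest written by [write_screen_report()]
#'
#' Reconstructs a [screen_config()] from the flat key-value manifest, so
#' a screen can be re-run from its own output.
#'
#' @param path Path to `manifest.txt`.
#' @return A `screen_config`.
#' @export
read_manifest <- function(path) {
  kv <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  m <- stats::setNames(kv$V2, kv$V1)
  num <- function(k) as.numeric(m[[k]])
  band <- as.numeric(strsplit(m[["palindrome_band"]], ",")[[1]])
  conf <- if (is.na(m["confounder_snps"]) || m[["confounder_snps"]] == "")
    character(0) else strsplit(m[["confounder_snps"]], ",")[[1]]
  screen_config(
    alpha = num("alpha"), fdr_method = m[["fdr_method"]],
    mr_tiers = strsplit(m[["mr_tiers"]], ",")[[1]],
    n_blocks = num("n_blocks"), mr_n_boot = num("mr_n_boot"),
    presso_n_sim = num("presso_n_sim"), sig_level = num("sig_level"),
    iv = iv_config(p_exposure_max = num("p_exposure_max"),
                   clump_r2 = num("clump_r2"), clump_kb = num("clump_kb"),
                   p_outcome_max = num("p_outcome_max"),
                   confounder_snps = conf,
                   proxy_r2_min = num("proxy_r2_min"),
                   palindrome_band = band),
    seed = num("seed"))
}
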