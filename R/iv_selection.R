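# Staged instrumental-variable selection for two-sample MR, with a full
# exclusion provenance log.
#
# The protocol, applied in order:
#   1. exposure association threshold (P < 1e-5 by default),
#   2. greedy LD clumping (r2 < 0.001 within 10,000 kb by default),
#   3. exclusion of variants associated with the outcome (P < 1e-5),
#   4. exclusion of variants on a user-supplied confounder list (a local
#      stand-in for interactive phenome-wide lookups),
#   5. harmonization, dropping palindromic variants of intermediate
#      allele frequency,
#   6. proxy substitution for instruments absent from the outcome study.

#' Instrument-selection configuration
#'
#' @param p_exposure_max Exposure association threshold.
#' @param clump_r2 Squared-correlation threshold for clumping.
#' @param clump_kb Clumping distance in kilobases.
#' @param p_outcome_max Outcome-association exclusion threshold.
#' @param confounder_snps Character vector of variant ids to exclude as
#'   confounder-associated (default empty).
#' @param proxy_r2_min Minimum r-squared for proxy substitution.
#' @param palindrome_band Intermediate-frequency band for palindromic
#'   variants.
#' @export
iv_config <- function(p_exposure_max = 1e-5, clump_r2 = 0.001,
                      clump_kb = 10000, p_outcome_max = 1e-5,
                      confounder_snps = character(0), proxy_r2_min = 0.8,
                      palindrome_band = c(0.42, 0.58)) {
  stopifnot(p_exposure_max > 0, p_exposure_max <= 1,
            clump_r2 >= 0, clump_r2 <= 1, clump_kb > 0,
            p_outcome_max > 0, p_outcome_max <= 1,
            proxy_r2_min >= 0, proxy_r2_min <= 1)
  structure(list(p_exposure_max = p_exposure_max, clump_r2 = clump_r2,
                 clump_kb = clump_kb, p_outcome_max = p_outcome_max,
                 confounder_snps = confounder_snps,
                 proxy_r2_min = proxy_r2_min,
                 palindrome_band = palindrome_band),
            class = "iv_config")
}

#' Greedy LD clumping
#'
#' Repeatedly keeps the remaining candidate with the smallest p-value and
#' discards every other remaining candidate on the same chromosome within
#' `distance_kb` whose panel r-squared with it is at least `r2_thresh`.
#' Candidates absent from the panel cannot be assessed for LD; they are
#' kept with a `no_ld_info` flag rather than dropped.
#'
#' @param candidates data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `pvalue`.
#' @param panel A `ref_panel` (or `NULL`: every candidate is kept
#'   flagged).
#' @param r2_thresh,distance_kb Clumping thresholds.
#' @return List with `kept` (candidates plus `no_ld_info`) and `removed`
#'   (`snp_id`, `index_snp` that displaced it).
#' @export
clump <- function(candidates, panel, r2_thresh = 0.001, distance_kb = 10000) {
  cand <- as.data.frame(candidates, stringsAsFactors = FALSE)
  stopifnot(all(c("snp_id", "chrom", "pos", "pvalue") %in% names(cand)))
  k <- nrow(cand)
  in_panel <- if (is.null(panel)) rep(FALSE, k) else
    cand$snp_id %in% colnames(panel$geno)
  ord <- order(cand$pvalue, cand$snp_id)
  status <- rep("pending", k)
  removed_by <- rep(NA_character_, k)
  for (i in ord) {
    if (status[i] != "pending") next
    status[i] <- "kept"
    if (!in_panel[i]) next
    gi <- panel$geno[, cand$snp_id[i]]
    for (j in seq_len(k)) {
      if (status[j] != "pending" || !in_panel[j]) next
      if (cand$chrom[j] != cand$chrom[i]) next
      if (abs(cand$pos[j] - cand$pos[i]) > distance_kb * 1000) next
      r2 <- stats::cor(gi, panel$geno[, cand$snp_id[j]])^2
      if (is.finite(r2) && r2 >= r2_thresh) {
        status[j] <- "removed"
        removed_by[j] <- cand$snp_id[i]
      }
    }
  }
  kept <- cand[status == "kept", , drop = FALSE]
  kept$no_ld_info <- !in_panel[status == "kept"]
  rownames(kept) <- NULL
  list(kept = kept,
       removed = data.frame(snp_id = cand$snp_id[status == "removed"],
                            index_snp = removed_by[status == "removed"],
                            stringsAsFactors = FALSE))
}

#' Find a proxy variant in high LD with a target variant
#'
#' Searches the reference panel for the variant with the largest
#' r-squared with `snp` (at least `r2_min`) among variants present in
#' `target`. Ties are broken by smaller base-pair distance, then by
#' lexicographic identifier.
#'
#' @param snp Variant identifier to proxy.
#' @param target A `sumstats` object the proxy must be present in.
#' @param panel A `ref_panel` containing `snp`.
#' @param r2_min Minimum acceptable r-squared.
#' @return List with `proxy` (id or `NA`), `r2`, `r_sign` (sign of the
#'   dosage correlation, used to orient the proxy's effect) and `reason`
#'   when no proxy is found.
#' @export
find_proxy <- function(snp, target, panel, r2_min = 0.8) {
  stopifnot(inherits(target, "sumstats"))
  if (is.null(panel) || !(snp %in% colnames(panel$geno))) {
    return(list(proxy = NA_character_, r2 = NA_real_, r_sign = NA_real_,
                reason = "absent_from_panel"))
  }
  cand <- setdiff(intersect(colnames(panel$geno), target$records$snp_id), snp)
  if (length(cand) == 0) {
    return(list(proxy = NA_character_, r2 = NA_real_, r_sign = NA_real_,
                reason = "no_candidate_in_target"))
  }
  g0 <- panel$geno[, snp]
  r <- as.vector(stats::cor(g0, panel$geno[, cand, drop = FALSE]))
  r2 <- r^2
  ok <- is.finite(r2) & r2 >= r2_min
  if (!any(ok)) {
    return(list(proxy = NA_character_, r2 = NA_real_, r_sign = NA_real_,
                reason = "no_proxy_above_threshold"))
  }
  pos0 <- panel$variants$pos[match(snp, panel$variants$snp_id)]
  posc <- panel$variants$pos[match(cand, panel$variants$snp_id)]
  dist <- abs(posc - pos0)
  o <- order(-r2, dist, cand)
  best <- o[ok[o]][1]
  list(proxy = cand[best], r2 = r2[best], r_sign = sign(r[best]),
       reason = NULL)
}

#' Select and harmonize MR instruments with full provenance
#'
#' Applies the staged quality-control protocol (see the module header and
#' the package vignette) and returns the surviving instruments aligned to
#' the exposure's effect-allele frame, together with an exclusion log
#' attributing every removal to a step and reason. Conservation holds by
#' construction: every candidate passing the exposure threshold appears
#' exactly once across kept instruments and the exclusion log.
#'
#' Proxy orientation caveat: reference-panel dosages carry no allele
#' labels, so a proxy's outcome effect is oriented by the sign of its
#' dosage correlation with the original instrument, assuming both
#' dosages count the respective study's effect allele.
#'
#' @param exposure,outcome `sumstats` objects.
#' @param panel A `ref_panel` used for clumping and proxy search (may be
#'   `NULL`).
#' @param cfg An [iv_config()].
#' @return An `iv_set`: list with `instruments` (data.frame `snp_id`,
#'   `ea`, `oa`, `beta_exp`, `se_exp`, `p_exp`, `beta_out`, `se_out`,
#'   `p_out`, `eaf`, `proxy_used`, `proxy_snp`, `no_ld_info`, `action`),
#'   `exclusions` (`snp_id`, `step`, `reason`), `config` and `k`.
#' @export
select_instruments <- function(exposure, outcome, panel = NULL,
                               cfg = iv_config()) {
  stopifnot(inherits(exposure, "sumstats"), inherits(outcome, "sumstats"))
  ex <- exposure$records
  logs <- list()
  add_log <- function(ids, step, reason) {
    if (length(ids) > 0) {
      logs[[length(logs) + 1]] <<- data.frame(
        snp_id = ids, step = step, reason = reason, stringsAsFactors = FALSE)
    }
  }
  fatal <- function(step, what) {
    stop(sprintf("empty-instrument error at step %d (%s)", step, what),
         call. = FALSE)
  }

  # step 1: exposure association threshold
  cand <- ex[!is.na(ex$pvalue) & ex$pvalue < cfg$p_exposure_max, , drop = FALSE]
  if (nrow(cand) == 0) fatal(1, "exposure p-value threshold")
  n_candidates <- nrow(cand)

  # step 2: LD clumping
  cl <- clump(cand[, c("snp_id", "chrom", "pos", "pvalue")], panel,
              cfg$clump_r2, cfg$clump_kb)
  add_log(cl$removed$snp_id, 2L,
          paste0("clumped_with:", cl$removed$index_snp))
  keep_ids <- cl$kept$snp_id
  no_ld <- stats::setNames(cl$kept$no_ld_info, cl$kept$snp_id)
  if (length(keep_ids) == 0) fatal(2, "LD clumping")

  # step 3: outcome-association exclusion
  op <- outcome$records$pvalue[match(keep_ids, outcome$records$snp_id)]
  out_assoc <- !is.na(op) & op < cfg$p_outcome_max
  add_log(keep_ids[out_assoc], 3L, "outcome_associated")
  keep_ids <- keep_ids[!out_assoc]
  if (length(keep_ids) == 0) fatal(3, "outcome-association exclusion")

  # step 4: confounder-list exclusion
  conf <- keep_ids %in% cfg$confounder_snps
  add_log(keep_ids[conf], 4L, "confounder_associated")
  keep_ids <- keep_ids[!conf]
  if (length(keep_ids) == 0) fatal(4, "confounder exclusion")

  # step 6 (identification): instruments absent from the outcome get a
  # proxy before harmonization
  present <- keep_ids %in% outcome$records$snp_id
  proxy_map <- stats::setNames(rep(NA_character_, length(keep_ids)), keep_ids)
  proxy_sign <- stats::setNames(rep(1, length(keep_ids)), keep_ids)
  for (id in keep_ids[!present]) {
    pr <- find_proxy(id, outcome, panel, cfg$proxy_r2_min)
    if (is.na(pr$proxy)) {
      add_log(id, 6L, paste0("missing_from_outcome:", pr$reason))
    } else {
      proxy_map[id] <- pr$proxy
      proxy_sign[id] <- pr$r_sign
    }
  }
  dropped6 <- keep_ids[!present & is.na(proxy_map[keep_ids])]
  keep_ids <- setdiff(keep_ids, dropped6)
  if (length(keep_ids) == 0) fatal(6, "proxy search")

  # step 5: harmonization (palindromic/intermediate and allele mismatch)
  direct_ids <- keep_ids[keep_ids %in% outcome$records$snp_id &
                           is.na(proxy_map[keep_ids])]
  rows <- list()
  if (length(direct_ids) > 0) {
    sub_exp <- as_sumstats(ex[ex$snp_id %in% direct_ids, , drop = FALSE],
                           trait = exposure$trait,
                           n_default = exposure$n_default)
    sub_out <- as_sumstats(
      outcome$records[outcome$records$snp_id %in% direct_ids, , drop = FALSE],
      trait = outcome$trait, n_default = outcome$n_default)
    hp <- harmonize_pair(sub_exp, sub_out, cfg$palindrome_band)
    add_log(hp$log$snp_id, 5L, hp$log$reason)
    if (nrow(hp$pairs) > 0) {
      h <- hp$pairs
      h$proxy_used <- FALSE
      h$proxy_snp <- NA_character_
      rows[[length(rows) + 1]] <- h
    }
  }
  proxied_ids <- keep_ids[!is.na(proxy_map[keep_ids])]
  for (id in proxied_ids) {
    pid <- proxy_map[[id]]
    er <- ex[ex$snp_id == id, ]
    or_ <- outcome$records[outcome$records$snp_id == pid, ]
    pal <- is_palindromic(or_$effect_allele, or_$other_allele, or_$eaf,
                          cfg$palindrome_band)
    if (pal$intermediate) {
      add_log(id, 5L, "proxy_palindromic_intermediate")
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      snp_id = id, ea = er$effect_allele, oa = er$other_allele,
      beta_exp = er$beta, se_exp = er$se, p_exp = er$pvalue,
      beta_out = proxy_sign[[id]] * or_$beta, se_out = or_$se,
      p_out = or_$pvalue, eaf = er$eaf, action = "proxy",
      proxy_used = TRUE, proxy_snp = pid, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) fatal(5, "harmonization")
  instruments <- do.call(rbind, rows)
  instruments <- instruments[match(
    intersect(cand$snp_id, instruments$snp_id), instruments$snp_id), ]
  instruments$no_ld_info <- unname(no_ld[instruments$snp_id])
  rownames(instruments) <- NULL

  exclusions <- if (length(logs)) do.call(rbind, logs) else
    data.frame(snp_id = character(0), step = integer(0),
               reason = character(0), stringsAsFactors = FALSE)
  stopifnot(nrow(instruments) + nrow(exclusions) == n_candidates)
  structure(list(instruments = instruments, exclusions = exclusions,
                 config = cfg, k = nrow(instruments),
                 n_candidates = n_candidates),
            class = "iv_set")
}

#' @export
print.iv_set <- function(x, ...) {
  cat(sprintf("<iv_set> %d instruments kept of %d candidates (%d excluded)\n",
              x$k, x$n_candidates, nrow(x$exclusions)))
  if (any(x$instruments$proxy_used))
    cat(" proxies:", sum(x$instruments$proxy_used), "\n")
  invisible(x)
}

#' Instrument-strength report
#'
#' Per-instrument F-statistics `(beta_exp/se_exp)^2` and their mean.
#' Reported for transparency; no strength filter is applied by the
#' selection protocol.
#'
#' @param iv An `iv_set`.
#' @return List with `f` (per-instrument, named) and `mean_f`.
#' @export
iv_strength <- function(iv) {
  f <- (iv$instruments$beta_exp / iv$instruments$se_exp)^2
  names(f) <- iv$instruments$snp_id
  list(f = f, mean_f = mean(f))
}

#' Write an instrument set and its exclusion log
#'
#' The instruments go to `path`, the exclusion log to
#' `paste0(path, ".log")` with every configured threshold echoed in
#' comment lines of the log header.
#'
#' @param iv An `iv_set`.
#' @param path Output path.
#' @export
write_iv_set <- function(iv, path) {
  data.table::fwrite(iv$instruments, path, sep = "\t", na = "NA", quote = FALSE)
  logpath <- paste0(path, ".log")
  cfg <- iv$config
  hdr <- c(sprintf("# p_exposure_max\t%g", cfg$p_exposure_max),
           sprintf("# clump_r2\t%g", cfg$clump_r2),
           sprintf("# clump_kb\t%g", cfg$clump_kb),
           sprintf("# p_outcome_max\t%g", cfg$p_outcome_max),
           sprintf("# proxy_r2_min\t%g", cfg$proxy_r2_min),
           sprintf("# palindrome_band\t%g,%g", cfg$palindrome_band[1],
                   cfg$palindrome_band[2]),
           sprintf("# confounder_snps\t%s",
                   paste(cfg$confounder_snps, collapse = ",")))
  writeLines(c(hdr, "snp_id\tstep\treason",
               sprintf("%s\t%d\t%s", iv$exclusions$snp_id,
                       iv$exclusions$step, iv$exclusions$reason)), logpath)
  invisible(path)
}
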