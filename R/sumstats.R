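# GWAS summary-statistics container, reading, validation and pairwise
# harmonization.
#
# A `sumstats` object is a list with components
#   trait     : trait label,
#   records   : data.frame with one row per variant and columns
#               snp_id, chrom, pos, effect_allele, other_allele, eaf,
#               beta, se, pvalue, n,
#   n_default : sample size used where per-variant n is missing,
#   drops     : data.frame logging rows removed during validation
#               (snp_id, reason),
#   notes     : character vector of validation warnings (e.g. p-vs-z
#               discrepancies).

SUMSTATS_COLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pvalue", "n")

# Relative tolerance for the p-value vs z-score consistency check.
P_Z_TOLERANCE <- 1e-3

#' Construct a validated summary-statistics object
#'
#' Validates a per-variant association table and returns a `sumstats`
#' object. Rows violating hard invariants (non-ACGT or identical alleles,
#' non-positive or non-finite standard error, non-finite effect size,
#' p-value outside (0, 1], duplicated or missing identifier) are dropped
#' and logged with a machine-readable reason. Alleles are upper-cased,
#' missing p-values are filled from the z-score as `2 * pnorm(-|beta/se|)`,
#' and reported p-values that disagree with the z-score by more than a
#' relative `1e-3` are flagged in `notes` but never altered.
#'
#' @param records data.frame with columns `snp_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se` (mandatory) and optionally `chrom`,
#'   `pos`, `eaf`, `pvalue`, `n`.
#' @param trait Trait label.
#' @param n_default Sample size substituted where per-variant `n` is
#'   missing (may be `NA` if `n` is complete).
#' @return A `sumstats` object.
#' @export
as_sumstats <- function(records, trait = "trait", n_default = NA_real_) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  mandatory <- c("snp_id", "effect_allele", "other_allele", "beta", "se")
  missing_cols <- setdiff(mandatory, names(records))
  if (length(missing_cols) > 0) {
    stop("summary-statistics format error: missing mandatory column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(SUMSTATS_COLS, names(records))) {
    records[[col]] <- if (col %in% c("chrom", "snp_id")) NA_character_ else NA_real_
  }
  records <- records[, SUMSTATS_COLS]
  records$snp_id <- as.character(records$snp_id)
  records$chrom <- as.character(records$chrom)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pvalue", "n")) {
    records[[col]] <- as.numeric(records[[col]])
  }

  drops <- list()
  note <- character(0)
  flag_drop <- function(bad, reason) {
    bad[is.na(bad)] <- FALSE
    if (any(bad)) {
      drops[[length(drops) + 1]] <<- data.frame(
        snp_id = records$snp_id[bad], reason = reason,
        stringsAsFactors = FALSE)
    }
    bad
  }

  bad <- flag_drop(is.na(records$snp_id) | records$snp_id == "", "missing_id")
  bad <- bad | flag_drop(!bad & duplicated(records$snp_id), "duplicate_id")
  valid_allele <- function(a) !is.na(a) & a %in% c("A", "C", "G", "T")
  bad <- bad | flag_drop(!bad & !(valid_allele(records$effect_allele) &
                                    valid_allele(records$other_allele)),
                         "invalid_allele")
  bad <- bad | flag_drop(!bad & records$effect_allele == records$other_allele,
                         "identical_alleles")
  bad <- bad | flag_drop(!bad & (!is.finite(records$se) | records$se <= 0),
                         "nonpositive_se")
  bad <- bad | flag_drop(!bad & !is.finite(records$beta), "nonfinite_beta")
  bad <- bad | flag_drop(!bad & !is.na(records$pvalue) &
                           (records$pvalue <= 0 | records$pvalue > 1),
                         "invalid_pvalue")

  records <- records[!bad, , drop = FALSE]
  if (nrow(records) == 0) {
    stop("empty-input error: no valid summary-statistics rows", call. = FALSE)
  }

  # eaf outside [0,1] is set to missing rather than dropping the row
  bad_eaf <- !is.na(records$eaf) & (records$eaf < 0 | records$eaf > 1)
  if (any(bad_eaf)) {
    records$eaf[bad_eaf] <- NA_real_
    note <- c(note, sprintf("%d allele frequencies outside [0,1] set to missing",
                            sum(bad_eaf)))
  }

  z <- records$beta / records$se
  p_from_z <- two_sided_p(z)
  fill <- is.na(records$pvalue)
  records$pvalue[fill] <- p_from_z[fill]
  chk <- !fill & p_from_z > 0
  rel <- abs(records$pvalue[chk] - p_from_z[chk]) / p_from_z[chk]
  n_discrepant <- sum(rel > P_Z_TOLERANCE, na.rm = TRUE)
  if (n_discrepant > 0) {
    note <- c(note, sprintf(
      "%d p-values disagree with beta/se z-scores beyond relative %g (left as reported)",
      n_discrepant, P_Z_TOLERANCE))
  }
  records$n[is.na(records$n)] <- n_default
  rownames(records) <- NULL

  structure(list(
    trait = trait,
    records = records,
    n_default = n_default,
    drops = if (length(drops)) do.call(rbind, drops) else
      data.frame(snp_id = character(0), reason = character(0),
                 stringsAsFactors = FALSE),
    notes = note
  ), class = "sumstats")
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("<sumstats> trait '%s': %d variants (%d dropped at read)\n",
              x$trait, nrow(x$records), nrow(x$drops)))
  if (length(x$notes)) cat(" notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Number of variants in a summary-statistics object
#' @param ss A `sumstats` object.
#' @export
n_variants <- function(ss) nrow(ss$records)

#' Read GWAS summary statistics from tab-separated text
#'
#' Reads a (possibly gzip-compressed) tab-separated table with a header
#' row, renames columns according to `dialect`, and validates the result
#' via [as_sumstats()]. The dialect mechanism lets files from different
#' GWAS pipelines (which disagree on column naming) load without editing.
#'
#' @param path Path to the file.
#' @param dialect Named character vector mapping standard column names
#'   (`snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pvalue`, `n`) to the column names used in the file.
#'   Standard names already present in the file need not be mapped.
#' @param trait Trait label attached to the result.
#' @param n_default Sample size for rows with missing `n`.
#' @return A `sumstats` object; dropped rows are logged in `$drops`.
#' @export
read_sumstats <- function(path, dialect = NULL, trait = "trait",
                          n_default = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, showProgress = FALSE)
  if (!is.null(dialect)) {
    bad_map <- setdiff(unname(dialect), names(dt))
    if (length(bad_map) > 0) {
      stop("summary-statistics format error: mapped column(s) absent from file: ",
           paste(bad_map, collapse = ", "), call. = FALSE)
    }
    for (std in names(dialect)) {
      names(dt)[names(dt) == dialect[[std]]] <- std
    }
  }
  as_sumstats(dt, trait = trait, n_default = n_default)
}

#' Write summary statistics as tab-separated text
#' @param ss A `sumstats` object.
#' @param path Output path (`.gz` suffix compresses).
#' @export
write_sumstats <- function(ss, path) {
  data.table::fwrite(ss$records, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Flag palindromic variants and intermediate allele frequency
#'
#' A variant is palindromic when its alleles are reverse complements
#' ({A,T} or {C,G}), so strand orientation cannot be resolved from the
#' alleles alone. For palindromic variants the effect-allele frequency is
#' the only harmonization signal, and it is uninformative near 0.5:
#' frequencies inside `band` (or missing) are flagged intermediate.
#'
#' @param effect_allele,other_allele Character vectors of single bases.
#' @param eaf Effect-allele frequency (may be `NA`).
#' @param band Closed frequency interval treated as intermediate.
#' @return data.frame with logical columns `palindromic` and
#'   `intermediate` (intermediate implies palindromic).
#' @export
is_palindromic <- function(effect_allele, other_allele, eaf = NA_real_,
                           band = c(0.42, 0.58)) {
  ea <- toupper(effect_allele)
  oa <- toupper(other_allele)
  pal <- !is.na(ea) & !is.na(oa) & complement_allele(ea) == oa
  inter <- pal & (is.na(eaf) | (eaf >= band[1] & eaf <= band[2]))
  data.frame(palindromic = pal, intermediate = inter)
}

# Classify one outcome allele pair against the exposure frame.
# Returns an action string: keep / flip / complement / complement_flip /
# mismatch.
classify_alleles <- function(e1, o1, e2, o2) {
  if (e2 == e1 && o2 == o1) return("keep")
  if (e2 == o1 && o2 == e1) return("flip")
  ce2 <- complement_allele(e2)
  co2 <- complement_allele(o2)
  if (ce2 == e1 && co2 == o1) return("complement")
  if (ce2 == o1 && co2 == e1) return("complement_flip")
  "mismatch"
}

#' Harmonize an exposure-outcome pair of summary statistics
#'
#' Joins two studies on variant identifier and expresses both effects on
#' the exposure's effect-allele frame. Outcome rows whose alleles are
#' swapped relative to the exposure have their effect sign flipped and
#' frequency reflected; strand-complement labellings are mapped back
#' before the same rule. Palindromic variants cannot be resolved from
#' alleles: they are oriented by comparing which side of 0.5 the two
#' frequencies fall on, and dropped when either frequency is missing or
#' inside the intermediate band. Irreconcilable allele pairs are dropped.
#' Every dropped variant appears exactly once in the exclusion log.
#'
#' @param exposure,outcome `sumstats` objects.
#' @param palindrome_band Frequency interval treated as intermediate for
#'   palindromic variants.
#' @return A `harmonized_pair`: list with `pairs` (data.frame with columns
#'   `snp_id`, `ea`, `oa`, `beta_exp`, `se_exp`, `p_exp`, `beta_out`,
#'   `se_out`, `p_out`, `eaf`, `action`) and `log` (data.frame `snp_id`,
#'   `reason`).
#' @export
harmonize_pair <- function(exposure, outcome, palindrome_band = c(0.42, 0.58)) {
  stopifnot(inherits(exposure, "sumstats"), inherits(outcome, "sumstats"))
  ex <- exposure$records
  ou <- outcome$records
  shared <- intersect(ex$snp_id, ou$snp_id)
  if (length(shared) == 0) {
    stop("empty-overlap error: no shared variant identifiers", call. = FALSE)
  }
  ex <- ex[match(shared, ex$snp_id), ]
  ou <- ou[match(shared, ou$snp_id), ]

  k <- length(shared)
  action <- character(k)
  reason <- character(k)
  beta_out <- ou$beta
  eaf_out <- ou$eaf

  for (i in seq_len(k)) {
    e1 <- ex$effect_allele[i]; o1 <- ex$other_allele[i]
    e2 <- ou$effect_allele[i]; o2 <- ou$other_allele[i]
    pal <- complement_allele(e1) == o1
    if (pal) {
      # same allele set in any labelling?
      if (!setequal(c(e2, o2), c(e1, o1)) &&
          !setequal(c(complement_allele(e2), complement_allele(o2)), c(e1, o1))) {
        action[i] <- "drop"; reason[i] <- "allele_mismatch"; next
      }
      inter_exp <- is.na(ex$eaf[i]) ||
        (ex$eaf[i] >= palindrome_band[1] && ex$eaf[i] <= palindrome_band[2])
      inter_out <- is.na(ou$eaf[i]) ||
        (ou$eaf[i] >= palindrome_band[1] && ou$eaf[i] <= palindrome_band[2])
      if (inter_exp || inter_out) {
        action[i] <- "drop"; reason[i] <- "palindromic_intermediate"; next
      }
      # orient by frequency: the outcome's frequency of allele e1 (as
      # labelled) must sit on the same side of 0.5 as the exposure's eaf;
      # otherwise the labels refer to the opposite configuration.
      f_e1_out <- if (e2 == e1) ou$eaf[i] else 1 - ou$eaf[i]
      same_side <- (f_e1_out - 0.5) * (ex$eaf[i] - 0.5) > 0
      label_keep <- (e2 == e1)
      keep_orientation <- (label_keep && same_side) || (!label_keep && !same_side)
      if (keep_orientation) {
        action[i] <- "palindromic_keep"
      } else {
        action[i] <- "palindromic_flip"
        beta_out[i] <- -beta_out[i]
        eaf_out[i] <- 1 - eaf_out[i]
      }
      next
    }
    act <- classify_alleles(e1, o1, e2, o2)
    if (act == "mismatch") {
      action[i] <- "drop"; reason[i] <- "allele_mismatch"
    } else {
      action[i] <- act
      if (act %in% c("flip", "complement_flip")) {
        beta_out[i] <- -beta_out[i]
        eaf_out[i] <- 1 - eaf_out[i]
      }
    }
  }

  kept <- action != "drop"
  pairs <- data.frame(
    snp_id = shared[kept],
    ea = ex$effect_allele[kept],
    oa = ex$other_allele[kept],
    beta_exp = ex$beta[kept],
    se_exp = ex$se[kept],
    p_exp = ex$pvalue[kept],
    beta_out = beta_out[kept],
    se_out = ou$se[kept],
    p_out = ou$pvalue[kept],
    eaf = ex$eaf[kept],
    action = action[kept],
    stringsAsFactors = FALSE
  )
  log <- data.frame(snp_id = shared[!kept], reason = reason[!kept],
                    stringsAsFactors = FALSE)
  structure(list(pairs = pairs, log = log), class = "harmonized_pair")
}

#' @export
print.harmonized_pair <- function(x, ...) {
  cat(sprintf("<harmonized_pair> %d aligned variants, %d dropped\n",
              nrow(x$pairs), nrow(x$log)))
  invisible(x)
}

#' Write a harmonized pair table as tab-separated text
#' @param hp A `harmonized_pair`.
#' @param path Output path.
#' @export
write_harmonized_pair <- function(hp, path) {
  data.table::fwrite(hp$pairs, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
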