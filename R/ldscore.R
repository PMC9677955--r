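# Per-variant LD scores from a reference panel.
#
# The LD score of variant j is the sum over neighbouring variants k of
# the squared genotype correlation r2_jk, including the self term
# (r2_jj = 1), so a variant in full linkage equilibrium scores 1.

#' Compute per-variant LD scores from a reference panel
#'
#' For each variant j, sums squared Pearson genotype correlations with
#' every variant in its window, itself included. The window is the
#' variant's LD block when the panel carries block metadata (the
#' default), or a fixed flanking count of variants. The optional
#' small-sample adjustment replaces each `r2` with
#' `r2 - (1 - r2) / (n_ind - 2)`, the standard unbiasing for estimated
#' squared correlations; it can only lower scores.
#'
#' @param panel A `ref_panel`.
#' @param window `"block"` (use the panel's block structure) or
#'   `"count"` (a symmetric window of `count_window` variants each side).
#' @param count_window Flanking variant count for `window = "count"`.
#' @param adjust Apply the small-sample bias adjustment.
#' @return An `ld_scores` data.frame with columns `snp_id`, `chrom`,
#'   `pos`, `L2`. Zero-variance variants receive `NA` with a warning.
#' @export
compute_ld_scores <- function(panel, window = c("block", "count"),
                              count_window = 50, adjust = FALSE) {
  stopifnot(inherits(panel, "ref_panel"))
  window <- match.arg(window)
  if (window == "block" && is.null(panel$variants$block)) window <- "count"
  geno <- panel$geno
  n <- nrow(geno)
  m <- ncol(geno)
  vars <- apply(geno, 2, stats::var)
  degenerate <- vars == 0 | is.na(vars)
  if (any(degenerate)) {
    warning(sum(degenerate), " zero-variance variant(s) assigned missing LD score")
  }
  adj <- function(r2) if (adjust) r2 - (1 - r2) / (n - 2) else r2

  l2 <- rep(NA_real_, m)
  if (window == "block") {
    for (b in unique(panel$variants$block)) {
      idx <- which(panel$variants$block == b & !degenerate)
      if (length(idx) == 0) next
      r2 <- stats::cor(geno[, idx, drop = FALSE])^2
      l2[idx] <- rowSums(adj(r2))
    }
  } else {
    ok <- which(!degenerate)
    for (j in ok) {
      win <- max(1, j - count_window):min(m, j + count_window)
      win <- win[!degenerate[win]]
      r2 <- as.vector(stats::cor(geno[, j], geno[, win, drop = FALSE]))^2
      l2[j] <- sum(adj(r2))
    }
  }
  structure(data.frame(
    snp_id = panel$variants$snp_id,
    chrom = panel$variants$chrom,
    pos = panel$variants$pos,
    L2 = l2,
    stringsAsFactors = FALSE), class = c("ld_scores", "data.frame"))
}

#' Write LD scores in the conventional ldscore file layout
#' @param scores An `ld_scores` data.frame.
#' @param path Output path.
#' @export
write_ld_scores <- function(scores, path) {
  data.table::fwrite(as.data.frame(scores)[, c("snp_id", "chrom", "pos", "L2")],
                     path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read LD scores written by [write_ld_scores()]
#' @param path Input path.
#' @export
read_ld_scores <- function(path) {
  df <- data.table::fread(path, sep = "\t", data.table = FALSE)
  df$snp_id <- as.character(df$snp_id)
  df$chrom <- as.character(df$chrom)
  structure(df, class = c("ld_scores", "data.frame"))
}
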