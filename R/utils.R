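# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = .GlobalEnv)
    } else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  expr
}

# Derive a child seed from a master seed; keeps results reproducible when
# one master seed drives several independent random stages.  Stays within
# the 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647L)
}

# Closed-form weighted least squares of y on (1, x).  Returns coefficients
# and the unscaled inverse Gram entries needed for standard errors.
wls_line <- function(x, y, w) {
  sw   <- sum(w)
  swx  <- sum(w * x)
  swy  <- sum(w * y)
  swxx <- sum(w * x * x)
  swxy <- sum(w * x * y)
  d <- sw * swxx - swx^2
  if (!is.finite(d) || d <= 0) {
    stop("rank-deficient weighted regression: predictor has no variation", call. = FALSE)
  }
  slope <- (sw * swxy - swx * swy) / d
  intercept <- (swy - slope * swx) / sw
  # diagonal of (X'WX)^{-1}: [intercept, slope]
  list(slope = slope, intercept = intercept,
       var_slope_unit = sw / d, var_intercept_unit = swxx / d)
}

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

complement_allele <- function(a) unname(DNA_COMPLEMENT[a])

two_sided_p <- function(z) 2 * stats::pnorm(-abs(z))

# p-value floored away from zero, for generated tables whose z-scores
# would underflow the two-sided normal tail
floored_p <- function(z) pmax(two_sided_p(z), 1e-300)
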