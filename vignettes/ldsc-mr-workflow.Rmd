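---
title: "Genetic correlation screening and two-sample Mendelian randomization with ldscmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic correlation screening and two-sample Mendelian randomization with ldscmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ldscmr` implements a two-stage workflow for linking polygenic traits
using only GWAS summary statistics: an LD score regression screen that
estimates the genetic correlation of many exposures (for example,
microbial taxon abundances) with one outcome (for example, a
case-control disease trait), followed by two-sample Mendelian
randomization (MR) with a full sensitivity battery on the exposures
that pass the screen. A synthetic-data module generates summary
statistics with known heritability, genetic correlation, confounding
inflation and causal structure, so every stage of the pipeline can be
validated against ground truth without cohort data.

```{r setup}
library(ldscmr)
```

## The LD score regression model

For a polygenic trait measured in a GWAS of `N` individuals over `M`
variants, the expected association chi-square statistic of variant `j`
is

$$ E[\chi^2_j \mid \ell_j] = \frac{N h^2}{M}\,\ell_j + N a + 1, $$

where $\ell_j = \sum_k r^2_{jk}$ is the LD score of variant `j` (the
amount of genetic variation it tags, self-term included), $h^2$ is the
SNP heritability, and $a$ measures confounding inflation such as
cryptic relatedness or population stratification. Regressing
$\chi^2_j$ on $\ell_j$ therefore separates polygenic signal (the
slope) from confounding (the intercept): the fitted intercept minus
one estimates $N a$. For two traits, regressing the per-variant
z-score product $z_{1j} z_{2j}$ on $\ell_j$ estimates genetic
covariance via the analogous slope
$\sqrt{N_1 N_2}\,\rho_g \sqrt{h^2_1 h^2_2}/M$, and the genetic
correlation is the covariance normalized by the geometric mean of the
two heritabilities.

`estimate_h2()` and `estimate_rg()` implement these regressions by
weighted least squares. Numerical choices:

* **Weights.** Baseline heteroskedasticity weights `1/max(l, 1)`.
  The iterative variance-based reweighting used by some
  implementations is deliberately out of scope: the expectation model
  specifies the regression, not the weighting, and the baseline
  weights keep every fit a closed-form solve (`wls_line()`, verified
  against an independent normal-equations solution). The choice is
  recorded in fit metadata.
* **Intercept.** Always free, never constrained to 1, so confounding
  is always visible.
* **Uncertainty.** Delete-one-block jackknife over contiguous variant
  blocks (contiguity respects LD; 200 blocks by default, shrunk to
  `floor(n/50)` for small inputs). For the genetic correlation the
  *full ratio statistic* — both component heritabilities and the
  covariance — is re-fitted in every delete-block replicate, so the
  standard error includes heritability-estimation noise.
* **Degenerate inputs.** All-identical LD scores are a
  rank-deficiency error; a non-positive fitted component heritability
  makes the correlation undefined and is reported as an error rather
  than clamped. Estimates with `|rg| > 1.25` carry a quality flag but
  are never truncated.
* **Chi-square capping.** Off by default; an optional cap at
  `max(80, 0.001 N)` (the convention of the reference software) can
  be enabled, and trimming is logged in the fit.

```{r}
scores <- synthetic_ld_scores(5000, seed = 3)
sim <- simulate_bivariate_gwas(scores, bivariate_gwas_config(
  h2_1 = 0.4, h2_2 = 0.3, rg_true = 0.5, n1 = 20000, n2 = 20000, seed = 11))
estimate_rg(sim$ss1, sim$ss2, scores)
```

## The synthetic-data generators

`simulate_bivariate_gwas()` is *summary-statistics-first*: it draws
per-variant z-score pairs directly from the bivariate normal implied
by the expectation model above, then back-fills effect sizes as
$z/\sqrt{N}$ with standard errors $1/\sqrt{N}$. This is exact for the
first and second moments that LD score regression estimates, and it
makes desk-scale variant counts (thousands to tens of thousands)
meaningful — simulating individual-level phenotypes at realistic
genome scale would not add information to these moments. Confounding
is injected as a shared variance inflation, so the fitted intercept
targets $Na + 1$ exactly; a cross-trait intercept (sample overlap) is
exposed as a parameter but defaults to zero, matching non-overlapping
cohorts. An individual-level path (`simulate_panel()`, dosages 0/1/2
with block-exchangeable Gaussian-copula LD) exists for small oracle
tests of the LD-score computation, clumping and proxy search; note the
realized dosage correlation is attenuated relative to the latent
copula correlation because dosages are discrete.

What the generators deliberately do **not** emulate: LD-induced
correlation between the z-scores of nearby variants (each variant's
z-score is an independent draw given its LD score), realistic
microbiome abundance distributions (only their GWAS summaries matter
downstream), minor-allele-frequency-dependent architectures, and
liability-scale conversion for binary traits (everything is on the
observed scale). Passing tests therefore demonstrate correctness of
the estimators under the expectation model, not robustness to every
feature of real data.

`simulate_mr_scenario()` generates two-sample MR data with `k_iv`
instruments: true exposure effects with association z-scores drawn
from `instrument_z_range` (default 7–14, emulating instruments passing
a suggestive $10^{-5}$ screen; estimated exposure p-values are below
$10^{-5}$ *by construction*, with failing draws rejected and redrawn),
outcome effects `beta_causal * b_x + alpha + noise`, and latent direct
effects `alpha` following one of four pleiotropy modes: `none`,
`balanced` (centred on zero), `directional` (centred on
`pleiotropy_mean`), or `outlier` (zero except for planted outliers of
`outlier_multiple` outcome standard errors, i.e. that many Wald-ratio
standard errors). Direct effects are planted in the
exposure-increasing-allele frame — the frame in which "directional"
is meaningful and in which Egger regression operates — and recorded on
the measured allele in the truth record.

## Harmonization and instrument selection

`harmonize_pair()` joins two studies on variant identifier and aligns
the outcome to the exposure's effect-allele frame: swapped alleles
flip the effect sign and reflect the frequency, strand-complement
labellings are mapped back first, and irreconcilable pairs are
dropped. Palindromic variants (A/T, C/G) cannot be resolved from
alleles; they are oriented by comparing which side of 0.5 the two
frequencies fall on, and dropped when either frequency is missing or
inside the intermediate band (0.42–0.58, the conventional choice; the
protocol names the rule but no band). Positions are carried but never
used for matching — the variant identifier is the key.

`select_instruments()` applies a staged quality-control protocol, in
order: (1) exposure association threshold ($P < 10^{-5}$); (2) greedy
LD clumping ($r^2 < 0.001$ within 10,000 kb) against a reference
panel; (3) exclusion of variants associated with the outcome
($P < 10^{-5}$); (4) exclusion of variants on a user-supplied
confounder list — a local, reproducible stand-in for interactive
phenome-wide association lookups, empty by default; (5) the
palindromic/intermediate-frequency exclusion during harmonization
(palindromic variants with *informative* frequency are kept and
aligned — the protocol excludes only the intermediate-frequency ones);
(6) proxy substitution (panel $r^2 \ge 0.8$) for instruments absent
from the outcome study, replacing interactive LD-lookup services with
a panel search. Every removal is logged with its step and a
machine-readable reason, and conservation (`kept + excluded =
candidates`) is asserted inside the function.

Two open-ended points were resolved as follows. Candidates absent
from the reference panel cannot be clumped; they are kept with a
prominent `no_ld_info` flag rather than dropped (favouring recall — a
silent drop would bias screens of sparsely covered exposures).
Proxy orientation: panel dosages carry no allele labels, so a proxy's
outcome effect is oriented by the sign of its dosage correlation with
the original instrument; this is an approximation, stated in the
documentation. Instrument strength (F-statistics) is reported by
`iv_strength()` for transparency but no strength filter is applied,
since the selection protocol does not include one.

## The five estimators

All methods share the per-instrument Wald ratio
$\hat\beta_j = \beta_{out,j}/\beta_{exp,j}$ with first-order standard
error $se_{out,j}/|\beta_{exp,j}|$ (the delta-method default of the
two-sample MR ecosystem; a second-order version is available behind a
flag).

* **Random-effects IVW** (the primary method): inverse-variance
  weighted mean; under heterogeneity the standard error is inflated by
  $\sqrt{Q/(k-1)}$, floored at 1 (multiplicative random effects —
  never deflated).
* **Egger regression**: weighted regression of outcome on exposure
  effects with a free intercept, after orienting all pairs to
  non-negative exposure effects; the slope is the causal estimate
  under the InSIDE assumption and the intercept measures average
  directional pleiotropy. Overdispersion is multiplicative with floor
  1, consistent with the IVW convention.
* **Weighted median**: weighted 50th percentile of the sorted ratios
  with linear interpolation across the cumulative-weight 0.5
  boundary; consistent when at least half the weight is valid.
* **Simple and weighted mode**: Gaussian kernel-density mode of the
  ratios (equal weights / inverse-variance weights), bandwidth
  `bandwidth_factor * 0.9 * mad * k^(-1/5)`; when all ratios coincide
  the common ratio is returned directly.

P-values are two-sided normal for every method (bootstrap-standard-
error based for the median and modes; `n_boot = 1000` by default, all
seeds surfaced). A 500-replicate calibration check showed the normal
Egger intercept test rejecting at 6–7% under balanced pleiotropy —
inside the acceptance band — so the simpler normal convention is kept
throughout rather than switching the Egger tests to a t reference.

## Sensitivity battery

`sensitivity_report()` bundles Cochran's Q for the IVW fit (df
$k-1$), Rucker's Q for the Egger fit (df $k-2$; never exceeds
Cochran's Q because the free intercept can only reduce the weighted
residual sum), the Egger intercept test, and a simulation-based
residual battery (`mr_presso()`, $k \ge 4$): the observed weighted
residual sum of squares of leave-one-out IVW predictions is compared
against `n_sim` parametric simulations under no pleiotropy (global
test), each instrument's residual against its own simulated reference
with Bonferroni correction (outlier test), and the relative shift of
the IVW estimate after removing flagged outliers against a
subset-resampling distribution (distortion test). When no outlier is
flagged the distortion test reports the conventional `NA` marker.
This package follows the canonical role assignment — the global test
detects horizontal pleiotropy, the distortion test quantifies the
estimate shift after outlier removal — noting that these two labels
are sometimes interchanged in applied reports.

## The two-stage screen

`run_screen()` estimates the genetic correlation of every exposure
with the outcome, assigns tiers — `significant`
($p \le \alpha/n$, the Bonferroni threshold), `suggestive`
($\alpha/n < p \le \alpha$), `null` — attaches Benjamini–Hochberg
q-values (ties are reported as-is; a screen of many weak signals
naturally produces long runs of tied q-values), and runs the full
instrument-selection, five-estimator and sensitivity battery on every
exposure in a triggering tier (suggestive and significant by
default). Exposure-level failures (say, a non-positive fitted
heritability) become tier `null` with a reason column, so screens
never silently shrink. Given identical inputs, configuration and
master seed the report is byte-identical, and `manifest.txt` written
by `write_screen_report()` suffices to reconstruct the configuration
(`read_manifest()`).

This package is library-first: the exported functions compose the
whole pipeline in a few lines (as above and in the README), and the
report writers produce the flat tab-separated tables a downstream
plotting or reporting tool consumes.

## Validation design and problem sizes

The test suite validates each stage against independent oracles:
brute-force pairwise $r^2$ summation for LD scores, normal-equations
solves for every weighted regression, hand-enumerated jackknife and
weighted-median cases, an independently coded greedy-clumping oracle,
and exhaustive proxy search. Statistical acceptance checks run at
these scales, chosen to keep Monte-Carlo error well inside the
asserted tolerances: genetic-correlation recovery with $M = 20{,}000$
variants and $N = 20{,}000$ per study over 200 replicates; estimator
recovery and test calibration over 500 replicates at $k = 30$ (or 20)
instruments; outlier detection over 200 replicates at
`n_sim = 1000`; and the end-to-end screen over 100 replicates.

The weighted-median robustness check uses strong instruments
(`instrument_z_range = c(70, 140)`): at the default suggestive-screen
strength ($z \in (7, 14)$) the valid instruments' own ratio noise is
of order $1/z \approx 0.1$, and the weighted 0.5-quantile of a
contaminated sample sits about one ratio standard error above the
valid-cluster centre — a finite-sample property of the estimator that
is independent of GWAS sample size (at fixed instrument z-score) and
would swamp a tight recovery tolerance. Strong instruments isolate
the property under test: robustness to 40% invalid weight.

The end-to-end screen battery (`simulate_screen_battery()`) emulates
a microbiome-GWAS-sized exposure cohort ($N = 2{,}000$) against a
larger outcome cohort ($N = 5{,}000$) over $M = 5{,}000$ variants
with LD scores in (1, 4), keeping the mean association chi-square
near 1.4 — a realistic inflation level at which a planted genetic
correlation of $-0.6$ is detectable but null exposures stay null. The
planted causal pathway runs through 15 large-effect instruments that
are deliberately excluded from the scored variant set, mirroring real
analyses in which the LD-score regression is restricted to a
well-behaved reference variant panel (large-effect outlier loci would
otherwise act as high-leverage points in the chi-square regression)
while MR uses the full GWAS.

## Known limitations

* No partitioned (annotation-stratified) heritability, no
  liability-scale conversion, and no modelling of sample overlap
  beyond reporting the fitted cross-trait intercept.
* The Wald-ratio standard error ignores exposure-effect uncertainty
  by default (first-order delta method); with weak instruments this
  understates heterogeneity slightly.
* Clumping and proxy search are only as good as the supplied panel;
  unpanelled candidates are kept but flagged, and proxy orientation
  relies on dosage-correlation sign.
* The screen runs one direction only (exposures toward outcome);
  reverse-direction MR and multivariable MR are out of scope.
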