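# ldscmr

LD score regression and two-sample Mendelian randomization for GWAS
summary statistics.

## What it is for

Epidemiological studies keep turning up associations between complex
traits — for instance between gut-microbial taxon abundances and
vascular disease — that observational designs cannot disentangle from
confounding and reverse causation. When genome-wide association study
(GWAS) summary statistics exist for both sides, two summary-level
techniques can: **LD score regression**, which separates polygenic
signal from confounding and estimates the genetic correlation between
traits, and **two-sample Mendelian randomization (MR)**, which uses
trait-associated variants as instrumental variables to estimate a
causal effect. `ldscmr` implements the complete chain — reading and
harmonizing summary statistics, LD-score computation, a
genetic-correlation screen with multiple-testing control, a staged
instrument-selection protocol, five MR estimators, and a
heterogeneity / pleiotropy sensitivity battery — together with a
synthetic-data module that generates summary statistics with known
ground truth, so every stage is testable offline.

## The models

**LD score regression.** For variant *j* with LD score
ℓⱼ = Σₖ r²ⱼₖ (the squared genotype correlations with its neighbours,
itself included), the expected association χ² statistic under a
polygenic model is

    E[χ²ⱼ | ℓⱼ] = N h² ℓⱼ / M + N a + 1

with sample size *N*, variant count *M*, SNP heritability *h²* and
confounding contribution *a*. The slope of a weighted regression of
χ² on ℓ estimates *h²*; the intercept minus one estimates the mean
confounding inflation *N a*. Regressing the cross-trait z-score
product z₁ⱼz₂ⱼ on ℓⱼ likewise estimates genetic covariance, and the
genetic correlation is r_g = gencov / √(h²₁ h²₂). Standard errors come
from a delete-one-block jackknife over contiguous variant blocks,
re-fitting the full ratio statistic in every replicate.

**Two-sample MR.** Each instrument's Wald ratio
β̂ⱼ = β_out,j / β_exp,j estimates the causal effect; the package
combines them with random-effects inverse-variance weighting (the
primary method), Egger regression (whose intercept measures
directional pleiotropy), the weighted median, and the simple and
weighted kernel-density modes. Cochran's and Rucker's Q, the Egger
intercept test, and a simulation-based residual battery (global /
outlier / distortion tests) diagnose heterogeneity and horizontal
pleiotropy.

## Worked example

Simulate a pair of genetically correlated traits, estimate the
correlation, then run the full MR battery on a scenario with a known
causal effect:

```r
library(ldscmr)

## genetic correlation: truth rg = 0.5, h2 = 0.4 / 0.3
scores <- synthetic_ld_scores(5000, seed = 3)
sim <- simulate_bivariate_gwas(scores, bivariate_gwas_config(
  h2_1 = 0.4, h2_2 = 0.3, rg_true = 0.5, n1 = 20000, n2 = 20000, seed = 11))
estimate_rg(sim$ss1, sim$ss2, scores)
#> <rg_estimate> rg = 0.5034 (SE 0.0149, p = 1.36e-250), gencov = 0.1735,
#>               h2 = 0.395/0.301, 5000 variants

## two-sample MR: truth beta_causal = 0.1, 20 instruments
s <- simulate_mr_scenario(mr_scenario(k_iv = 20, beta_causal = 0.1, seed = 5))
iv <- select_instruments(s$exposure, s$outcome)
mr_all(iv, n_boot = 1000, seed = 2)
#>            method nsnp   beta     se   pvalue   OR CI_low CI_high
#> 1          IVW-RE   20 0.0854 0.0205 0.000031 1.09  1.046    1.13
#> 2           Egger   20 0.1498 0.0898 0.095392 1.16  0.974    1.39
#> 3 weighted-median   20 0.0904 0.0267 0.000727 1.09  1.039    1.15
#> 4     simple-mode   20 0.0811 0.0426 0.056894 1.08  0.998    1.18
#> 5   weighted-mode   20 0.0823 0.0364 0.023961 1.09  1.011    1.17

sensitivity_report(iv, n_sim = 1000, seed = 4)
#> <sensitivity_report> Q = 13.440 (df 19, p = 0.815); Q' = 12.898 (df 18, p = 0.798)
#>  Egger intercept -0.005097 (SE 0.006926, p = 0.462); global p = 0.823; outliers: NA
```

The correlation estimate (0.503, jackknife SE 0.015) recovers the
planted 0.5; all five MR estimates sit near the planted causal effect
0.1 (odds ratios ≈ 1.09 per unit exposure), and the quiet sensitivity
battery (all p > 0.05, no flagged outliers) is exactly what a
pleiotropy-free scenario should produce.

The screening pipeline over many exposures is one call:

```r
b <- simulate_screen_battery(screen_battery_config(seed = 17))
report <- run_screen(b$outcome, b$exposures, b$scores, b$panel,
                     screen_config(seed = 17))
report$screen             # trait, rg, se, p, fdr, tier, reason
write_screen_report(report, "screen_out")
```

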