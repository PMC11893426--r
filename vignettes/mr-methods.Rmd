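---
title: "Methods: summary-statistics MR, mediation and PheWAS enrichment in mrpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: summary-statistics MR, mediation and PheWAS enrichment in mrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpipe)
```

# The model

Two-sample Mendelian randomization treats genetic variants as
instrumental variables for an exposure. For SNP $j$, let
$\hat\beta_{Xj} \pm \sigma_{Xj}$ be its association with the exposure in
one GWAS and $\hat\beta_{Yj} \pm \sigma_{Yj}$ its association with the
outcome in another. If the variant satisfies relevance (associated with
the exposure), independence (not associated with confounders) and
exclusion (no path to the outcome other than through the exposure), then
each Wald ratio $\hat\beta_{Yj}/\hat\beta_{Xj}$ estimates the same causal
effect $\theta$, and the estimators differ in how they pool ratios and in
which violations they tolerate:

- **IVW** is the weighted regression of $\hat\beta_Y$ on $\hat\beta_X$
  through the origin with weights $1/\sigma_{Yj}^2$ — efficient when all
  instruments are valid. We default to *multiplicative random effects*:
  the fixed-effects SE $1/\sqrt{\sum \hat\beta_{Xj}^2/\sigma_{Yj}^2}$ is
  inflated by $\max(1, \sqrt{Q/(n-1)})$, which keeps the point estimate
  and widens the interval under heterogeneity instead of discarding the
  estimator. A fixed-effects flag is available. With one SNP, IVW
  degenerates to the Wald ratio (with a warning).
- **MR-Egger** adds an intercept after orienting all exposure effects
  non-negative; the slope is consistent under InSIDE (instrument strength
  independent of direct effects) and the intercept estimates directional
  pleiotropy. SEs are inflated by $\max(1, \sqrt{RSS_w/(n-2)})$.
  Intercept and slope p-values are two-sided normal, consistent with the
  rest of the package.
- **Weighted median** interpolates the inverse-variance-weighted
  empirical CDF of ratios at 0.5 ($p_j = (\sum_{k\le j} w_k - w_j/2)/\sum
  w$, linear interpolation); consistent when valid instruments carry
  half the weight. The SE is a parametric bootstrap (resampling
  $\hat\beta_X$, $\hat\beta_Y$ from their sampling normals; 1000
  replicates, seeded).
- **Weighted mode** takes the argmax of a Gaussian-kernel weighted
  density of the ratios, bandwidth $0.9\,\mathrm{mad}(r)\,n^{-1/5}$ times
  a user factor. If the MAD is zero the mode is the value carrying the
  most weight. SE by the same bootstrap.

Heterogeneity is Cochran's $Q = \sum_j w_j (r_j - \hat\theta)^2$ on
first-order ratio weights $w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$, df
$n-1$. Leave-one-out recomputes the random-effects IVW per exclusion and
flags exclusions that change the sign of the estimate or nullify its
nominal significance. Binary-outcome effects are log-odds; reports show
$\mathrm{OR} = e^{\hat\theta}$ with the exact-quantile interval
$e^{\hat\theta \pm 1.959964\,se}$ (1.96 is never used internally;
published tables are matched at 4 decimals).

# MR-PRESSO

The global test asks whether the observed scatter around the fitted
slope exceeds what sampling noise explains. For each SNP the
leave-one-out IVW slope $\hat\theta_{-j}$ predicts
$\hat\beta_{Yj}$; the observed weighted residual sum of squares is
compared against $K$ datasets simulated under the null
($\beta^*_{Yj} \sim N(\hat\theta_{-j}\hat\beta_{Xj}, \sigma_{Yj})$,
$\beta^*_{Xj} \sim N(\hat\beta_{Xj}, \sigma_{Xj})$), with the add-one
correction $p = (1 + \#\{RSS^* \ge RSS\})/(K+1)$, so $p$ is never exactly
zero. Per-SNP outlier p-values compare each squared residual with its
simulated distribution and are flagged at the Bonferroni threshold
$0.05/n$. Because the smallest attainable simulation p-value is
$1/(K+1)$, flagging requires $K > 20n$; the function warns otherwise.
The distortion test compares
$(\hat\theta_\mathrm{raw}-\hat\theta_\mathrm{corrected})/|\hat\theta_\mathrm{corrected}|$
with the same statistic for random same-size SNP subsets. The pipeline
reports raw and outlier-corrected estimates side by side and never drops
SNPs silently.

# Harmonization rules

Outcome records are aligned to the exposure's effect allele:
identical pairs pass through; swapped pairs negate $\hat\beta_Y$ and
complement the frequency; otherwise strand complements are tried; any
remaining mismatch is dropped with reason `allele_mismatch`. Palindromic
SNPs (A/T, C/G) carry no strand information in their alleles, so they
are oriented by comparing which side of 0.5 the two effect-allele
frequencies fall on, and dropped as `ambiguous_palindrome` when either
frequency lies within the **ambiguity window 0.08** of 0.5 (i.e. in
(0.42, 0.58)) or is missing. The window is a conventional default and is
configurable (`eaf_window`); a `keep_palindromes` flag supports
sensitivity reruns. Non-palindromic SNPs never need frequencies.
Harmonization never touches the exposure side, and a scrambled-then-
harmonized dataset reproduces the original outcome effects exactly for
non-palindromic SNPs (the involution property tested in the suite).
Proxy substitution (off by default) replaces an instrument missing from
the outcome wholesale by its best LD partner with $r^2 > 0.8$ present in
both datasets; no allele bridging through LD signs is attempted.

# Thresholds and defaults

| Parameter | Default | Meaning |
|---|---|---|
| `p_instrument` | 1e-5 | instrument p-value screen |
| `clump_r2`, `clump_kb` | 0.001, 10000 | greedy LD clumping |
| `f_min` | 10 | per-SNP F = (β/se)² floor |
| `proxy_r2` | 0.8 | strict LD floor for proxies (off by default) |
| `eaf_window` | 0.08 | palindrome ambiguity half-width |
| `fdr_threshold`, `p_threshold` | 0.05, 0.05 | *significant* / *potential* tiers |
| `presso_k`, `n_boot` | 1000, 1000 | simulation and bootstrap sizes |
| `n_controls` | 4 | matched controls per PheWAS index SNP |
| `p_nominal` | 0.01 | PheWAS association carry-forward |
| `seed` | 20240101 | root seed; stages draw named sub-seeds |

F is enforced per SNP by default; the mean F of a selected set is also
obtainable from the `f_stat` column — the per-SNP rule is the stricter
and more common reading of the F ≥ 10 convention. Clumping is greedy by
ascending p with ties broken by SNP id, so results are invariant to input
order. BH-FDR families are always one exposure panel against one outcome,
never pooled across outcomes.

# Mediation

The two-step screen estimates exposure→mediator (step 1, on the
exposure's instruments) and mediator→outcome (step 2, on the mediator's
own instruments), carrying forward mediators nominally significant in
both. The indirect effect is the product of coefficients $ab$. Its SE is
the **exact** SD of a product of independent normal estimators,
$\sqrt{a^2\sigma_b^2 + b^2\sigma_a^2 + \sigma_a^2\sigma_b^2}$ — the
second-order cross term is included deliberately: it is what reproduces
published delta SEs that the first-order formula misses at this effect
scale. The mediation proportion is $100\,ab/\mathrm{total}$ with CI
obtained by scaling the indirect effect's Wald interval by the total
effect, treating the total as fixed. That choice reproduces published
proportion intervals exactly, but understates uncertainty when the total
effect is itself noisy — a documented limitation, not an oversight. Rows
where the indirect and total effects have opposite signs are labelled
*suppression*: the mediator works against the total effect rather than
transmitting it.

# What the synthetic generators emulate

`simulateGwasPair()` draws per-SNP MAF uniformly on (0.05, 0.5), sets
$\sigma = 1/\sqrt{2n\,\mathrm{maf}(1-\mathrm{maf})}$ (the
standardized-trait approximation, used for continuous and binary traits
alike), draws true instrument effects from $N(0, 0.05^2)$ resampled until
the true per-SNP F reaches 10, forms outcome effects
$\theta\beta_X + \alpha$, and adds sampling noise to both sides. Default
sample sizes mirror the data the pipeline targets: an Olink-scale pQTL
panel (n = 14824), a FinnGen-scale outcome (n = 73479) and a
metabolite-panel mediator (n = 8299). Pleiotropy models: `balanced`
(zero-mean $\alpha$), `directional` ($\alpha$ with nonzero mean relative
to the exposure-increasing allele), and `inside_violating` ($\alpha$
correlated with instrument strength at $\rho = 0.5$, the regime where
MR-Egger fails by construction). About 20% of SNPs get palindromic
allele pairs so harmonization drops are exercised.

The generators do **not** emulate: LD between instruments (LD matrices
are block-diagonal toys), binary-trait effective sample size
(case/control imbalance), population stratification, sample overlap
between the two GWAS, or winner's-curse selection in the source studies.
Passing tests therefore demonstrate correctness of the estimators and
plumbing under the stated sampling model, not robustness to everything
real data can do.

Two design notes on the recovery checks in the test suite:

- Ratio estimators attenuate by roughly $\bar F/(\bar F + 1)$ when the
  exposure effects carry sampling noise — a real property of MR, not a
  bug. Calibration checks (null uniformity, CI coverage) run at the
  moderate-strength condition (n = 20000/70000, 50 SNPs), where coverage
  is nominal. Point-recovery checks (the mediation proportion) run in a
  strong-instrument regime (mediator GWAS n = 100000, on the scale of
  modern metabolomic panels, with the known instrument sets) so that the
  $1/\bar F$ attenuation is small against the Monte-Carlo tolerance;
  at the weak study-scale mediator panel the same code shows the expected
  few-percent attenuation.
- The MR-PRESSO power check injects a 5× outcome-effect inflation into a
  50-SNP set with $\theta = 0.6$ and $K = 1000$: large enough for the
  outlier to be unambiguous, while keeping the contamination of the other
  SNPs' leave-one-out slopes — which produces false co-flags at very
  large $\theta$ — negligible, and with $K > 20n$ so the Bonferroni
  threshold is attainable.

# PheWAS enrichment

Each index SNP is matched to four controls drawn from an annotated pool:
MAF within ±0.05 (absolute — a relative ±5% of a rare allele would empty
the match set), and gene density, distance to the nearest gene and
LD-partner count (r² ≥ 0.5) each within ±50% relative. Controls are
sampled uniformly without replacement from the eligible set, seeded, and
removed from the pool between index SNPs; shortfalls are logged, not
fatal. Per trait, the counts of nominally associated (p < 0.01) index
versus control SNPs form a 2×2 table tested by a two-sided Fisher's exact
test (point-probability rule); p-values are BH-FDR adjusted across
traits. A trait with no associated SNP on either arm reports an `NA` odds
ratio and p = 1.

# Numerical and degenerate-input choices

- p-values of exactly 0 on input are floored to 1e-300 (downstream logs
  and quantiles stay finite); indels and monomorphic allele pairs are
  rejected with reason codes rather than coerced.
- Estimator minimum SNP counts: IVW 2 (1 falls back to Wald with a
  warning), Egger / weighted median / weighted mode 3, MR-PRESSO 4.
- Ties in clumping and proxy search break by p-value then lexicographic
  SNP id, making every selection deterministic.
- All bootstraps and simulations take explicit seeds; pipeline stages
  derive named sub-seeds from the single config seed, so whole runs are
  reproducible end to end.
- Weighted-mode bandwidth uses the MAD; an all-equal ratio vector (MAD
  0) returns the dominant value directly instead of a degenerate kernel.

# Known limitations

Multivariable MR, Steiger directionality filtering and
contamination-mixture estimators are out of scope (reverse causation is
addressed by bidirectional reruns instead). The proportion CI treats the
total effect as fixed. The simulation-based MR-PRESSO p-values are
Monte-Carlo estimates; two runs agree only under the same seed and K.
LD must be supplied (or simulated); the package computes none from
genotypes.

# Problem sizes used in the shipped checks

Calibration: 200 replicates of 50-SNP panels (null and $\theta = 0.3$).
MR-PRESSO power: 100 replicates, K = 1000. Mediation recovery: 300
replicates of 50+50-SNP triplets. Involution: one 1000-SNP panel.
Forward-screen orchestration tests run 9-exposure panels with reduced
bootstrap sizes. These sizes make the full suite complete in well under a
minute while leaving the Monte-Carlo assertions comfortably powered.
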