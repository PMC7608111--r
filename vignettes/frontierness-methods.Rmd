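---
title: "Frontierness: models, synthetic worlds, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frontierness: models, synthetic worlds, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frontierness)
```

This vignette is the package's own account of the science it implements:
the models, the synthetic data-generating process behind the test suite,
the numerical choices, and the places where the design was genuinely open.

## The two-stage model

The package works on a coarse raster lattice (row 1 = northernmost row,
cells addressed `(row, col)`). The start-year cropland state of pixel $i$
is a fraction $s_i \in [0,1]$ of its non-water land; analyses binarize it
at a threshold $\tau \in \{0.005, 0.10, 0.50\}$ with a strict inequality,
$y_i = \mathbf{1}\{s_i > \tau\}$. The strict form was chosen over an
inclusive one because a fraction *exceeding* the named percentage is the
cleaner reading of "more than x%"; `binarize()` exposes
`boundary = "inclusive"` for sensitivity work, and the boundary case is
unit-tested.

**Stage 1 — the null model.** Over all bioclimatically suitable pixels
(suitability strictly positive; ocean/nodata excluded), a single logistic
regression of $y$ on the classical term set

$$X_1 = \text{suit} + \text{access} + \text{steep} + \text{pop} +
\text{gdp} + 8 \text{ pairwise interactions}$$

is fit by maximum likelihood — no sub-sampling, no re-centering beyond the
global standardization. Every model variable (including start-year
cropland and, later, frontierness) is standardized to mean 0, SD 1 over
the suitable-pixel domain before entering any design matrix.

**Stage 2 — frontierness.** The response residual $y_i - \hat p_i$ is
divided by its SD over the domain:
$z_i = (y_i - \hat p_i)/\operatorname{sd}(y - \hat p)$. Classes are cut at
$|z| = 1$ and $2$: `pos2` ($z \ge 2$), `pos1` ($1 \le z < 2$), `neg1`
($-2 < z \le -1$), `neg2` ($z \le -2$), else `neutral`.

*Why response residuals?* "More cropland than predicted" is a
response-scale notion, and the response residual is its most literal
measurement. Pearson or deviance residuals would up-weight pixels with
extreme fitted probabilities, changing the meaning of "1 SD". The mean of
the response residuals is already ≈ 0 (the fitted intercept absorbs it),
so the score divides by the SD without re-centering. `fit_null()` stores
residuals so alternative standardizations can be layered on if needed.

Frontierness is computed once per threshold and then treated as a fixed
covariate: it is never recomputed inside sub-samples, because the proxy is
a property of the global start-year map, not of any particular sample.

## Ensembles, pseudo-R², and the model comparison

Expansion presences are globally rare, so all comparative modelling uses
balanced sub-samples: each replicate draws exactly `n_presence` presences
and `n_absence` absences (500/500 by default) without replacement,
independently across replicates. Replicate RNG streams are keyed by
`(seed, replicate_index)`, which makes replicates order-independent and
the whole ensemble bitwise reproducible. Within each replicate the
main-effect columns are re-centered to the sub-sample mean *before*
products are formed — the standard prescription for interaction models —
and only means are subtracted, never scales. Re-centering the mains and
then forming products keeps the model span identical to the raw
parametrization; interaction coefficients are unchanged, and main effects
are read at the sub-sample mean of their interaction partners.

Each replicate reports McFadden's pseudo-R², $1 - \ell/\ell_0$, with
$\ell_0$ the intercept-only log-likelihood of the same sample. Ensemble
summaries are the mean coefficient, the empirical 2.5%/97.5% percentiles
(the "95% interval" — percentile form chosen because the replicate
distribution is directly available and no normality assumption is
needed), and the mean pseudo-R² over converged replicates. Replicates
whose coefficients diverge (|β| > 25 or non-finite — the practical
signature of complete separation) are recorded but excluded from
summaries; an ensemble with more than 10% such replicates carries a
warning.

The with/without-frontierness comparison fits, per threshold, model 2
($X_1 + X_2$, where $X_2$ adds start-year cropland and its five
interactions with the $X_1$ mains) and model 3 ($X_1 + X_2 + X_3$, adding
frontierness and its cropland interaction) on *identical* replicate
sub-samples. Pairing was an open choice — the fitting could equally draw
fresh samples per model — but paired draws cannot bias either mean and
substantially reduce the variance of their difference, so the reported
gain is not inflated by sampling noise. Within a replicate, model 3 nests
model 2 on the same rows, so its in-sample log-likelihood is never lower;
the tests assert this exactly.

Logistic fitting itself is IRLS (`stats::glm.fit`) with tight tolerances;
a hand-written Newton–Raphson optimizer serves as an independent
cross-check in the test suite. Rank-deficient design columns (e.g. a
covariate that is identically zero) are reported as zero coefficients
rather than errors, so degenerate-covariate sanity checks behave.

## Overlap ratios

For a nonnegative value raster $v$, a selection $S$ and a domain $D$,

$$r = \frac{\sum_{S} v \,/\, \sum_{D} v}{|S| / |D|},$$

so $r = 1$ exactly when $v$ is uniformly distributed with respect to the
selection. For the deviance-class tables the value raster is $|z|$
restricted to the class — deviation-magnitude weighting, which matches a
"summed total value" reading and makes strong deviations count more. An
area-only mode (`mode = "area"`, 0/1 indicator) is provided because the
ratio can equally be read as comparing areas; both modes are tested, and
magnitude weighting is the default. Undefined cells (empty class, zero
total value) are reported as `NA`, never silently as zero. Ratios are
only ever formed between a deviance layer and an expansion map binarized
at the *same* threshold.

## The synthetic world

The generator exists so that every pipeline stage can be validated against
known ground truth without any external download. Its defaults define the
package's reference study conditions; they were chosen once — to produce a
world that is scientifically plausible *and* recoverable by the methods
under test — and then frozen.

- **Predictor fields.** Five independent stationary Gaussian fields
  (FFT-smoothed white noise; kernel SD $(L-1)/2$ for autocorrelation
  length $L$, default 10 cells on a 200×200 lattice), mapped onto
  plausible supports: suitability truncated at zero (the zero set defines
  the unsuitable mask), steepness squashed into $[0,1]$, and the
  socio-economic layers exponentiated to be nonnegative and mildly
  right-skewed (`exp(0.5z)`–`exp(0.6z)`; stronger skew was rejected
  because occasional extreme-leverage realizations made the gdp
  coefficient poorly identified at realistic sample sizes).
- **Extent process.** The linear predictor is the $X_1$ design at planted
  coefficients `beta_true` (defaults: intercept −7; mains 3.0, −2.4,
  −1.8, 1.8, 1.2; interactions ±0.02), plus a frontier boost
  $\gamma f_i$ ($\gamma = 9$) and a latent *standard logistic*
  disturbance. The logistic disturbance is deliberate: it makes the
  binarized extent an exact logistic GLM in the planted coefficients, so
  coefficient recovery is a well-posed check. Without any disturbance the
  binarized response would be a deterministic threshold of the linear
  predictor and every fit would separate. The fraction itself is
  `0.95 · plogis(·)` — the 0.95 squash keeps all three thresholds
  populated rather than saturating at exactly 1.
- **Planted interactions are weak by design.** Under sub-sample
  re-centering, a true interaction coefficient $\beta_{jk}$ contributes
  $\beta_{jk}\bar m_k$ to the fitted main effect $j$ (an exact
  reparametrization identity, with $\bar m_k$ the balanced-sample mean of
  the partner). Strong planted interactions would therefore make planted
  mains unrecoverable by construction; ±0.02 keeps that leakage an order
  of magnitude below the recovery tolerance.
- **Frontier field.** 25 Gaussian cluster kernels of scale 10 cells,
  truncated to zero beyond 4× the radius, seeded preferentially at
  moderate-suitability, poorly-accessible cells (probability ∝ rank
  product) — remote-but-workable land, which is where frontiers arise.
- **Expansion process.** Logit-linear in the same design at weak planted
  coefficients (intercept −8.5) plus a strong frontier term
  ($\lambda = 8$) and a tighter logistic disturbance (scale 0.3): the
  frontier process, not chance, decides where expansion lands. The
  resulting fraction is clipped to the land still available,
  $1 - s_i - \text{nonconvertible}_i - \text{protected}_i$, with urban
  capped by non-cropland land and protection applied to the remainder so
  per-cell fractions always sum to ≤ 1.
- **Masks.** Water and non-convertible fractions from thresholded smooth
  fields; protected patches as the top `protected_share` quantile of a
  smooth field (contiguous by construction).

What the generator does *not* emulate: spatially correlated response
noise (disturbances are independent across cells given the fields), real
predictor cross-correlations (fields are independent), measurement error
in the land-cover maps, and any temporal dynamics within the period. A
green test suite therefore demonstrates that the machinery recovers
planted structure under clean conditions — not that the substantive
conclusions would survive the messiness of real rasters.

### What the planted world reproduces

At the default conditions the pipeline reproduces the qualitative
signature the method is designed to detect, verified across seeds during
development and asserted at fixed seeds in the test suite: classical
predictors explain extent better than minor/major expansion; expansion is
over-represented in ≥1 SD positive-deviance pixels and under-represented
in negative-deviance pixels at the 0.5% and 10% thresholds; the
frontierness score rank-correlates with the planted frontier field
(Spearman ρ > 0.5 at the 10% threshold) and is uncorrelated with it when
the frontier boost is zero; and adding frontierness raises mean expansion
pseudo-R² by ≥ 0.05 at the 0.5% and 10% thresholds while leaving a
frontier-free world's models essentially unchanged.

### The recovery check and its coefficient regime

The parameter-recovery test plants a *moderate* coefficient vector (mains
|β| ≤ 1, intercept −2) in a world without frontier boost, and requires the
200-replicate ensemble's mean main effects to land within ±0.1 of truth.
The moderate regime is deliberate: balanced-subsample logistic MLE carries
a small-sample bias away from zero that grows with the strength of
discrimination — at the default study world's mains (|β| up to 3, chosen
so that the classical signal visibly dominates extent) that bias alone is
~3–5% of |β|, i.e. above a ±0.1 absolute band, even though the ensemble
is behaving exactly as theory predicts. Recovery is therefore verified
where the estimator is well-identified; the default world's stronger
coefficients are a separate choice serving the frontier-detection
scenarios.

## Numerical and interface choices

- **Thresholds** default to 0.5%, 10%, 50%; strict binarization;
  matched-threshold discipline throughout.
- **Availability** is fractional bookkeeping per coarse cell:
  `1 - cropland - nonconvertible - protected`, clipped at zero with a
  warning if inputs overlap inconsistently; a pixel enters the expansion
  domain when suitable and available ≥ τ.
- **Mosaic-type classes** are excluded from cropland by default at the
  fine scale; `mosaic_as_cropland = TRUE` in the aggregation functions
  mirrors the inclusive sensitivity convention.
- **Raster I/O** is the plain-text ESRI ASCII grid format (`read_grid()`
  / `write_grid()`), value-exact on round trip (17 significant digits)
  with an explicit nodata sentinel; every reduction masks nodata
  explicitly. Reprojection and resampling are out of scope — all layers
  in one analysis must share a lattice, and `assert_aligned()` enforces
  it.
- **Seeds.** One master seed fans out to named per-stage streams
  (`run_pipeline()`), and within ensembles to per-replicate streams, all
  kept inside 32-bit range. Identical configs give identical output
  checksums; the pipeline writes an md5 manifest to prove it.
- **Problem sizes.** The reference lattice is 200×200 (~33,000 suitable
  pixels) with 200-replicate ensembles; the pipeline demo runs 100×100
  with 100 replicates. Replicate counts are configurable up to the
  10,000/1,000 used in large production analyses; means stabilise far
  earlier, which is why the package defaults are smaller.

## Known limitations

- Standard errors ignore spatial autocorrelation; the balanced
  sub-sampling thins spatial structure but does not remove it. The
  empirical percentile intervals summarise between-replicate variability,
  not map-level uncertainty.
- The response-residual definition of frontierness compresses deviations
  at pixels with extreme fitted probabilities; alternative residual types
  would rank such pixels differently.
- Frontierness derived from a start-year map can only proxy *pre-existing*
  frontier momentum; a regime shift in where expansion happens would
  erode its value, and no test here can detect that.
- The generator's independence assumptions (between predictor fields, and
  between cells given the fields) make recovery easier than real data
  would; treat the planted-world results as validation of machinery, not
  as effect-size guidance.
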