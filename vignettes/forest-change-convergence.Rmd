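---
title: "Methods: satellite–local knowledge convergence analysis of forest change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: satellite–local knowledge convergence analysis of forest change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestconverge)
```

## The problem

Classified satellite time series and community recall are two measurements
of the same quantity — the trajectory of a forest patch — made with very
different instruments. The satellite instrument has known blind spots
(degradation below the canopy-cover detection threshold of 30 m pixels);
the survey instrument has its own (recall bias, social desirability,
heterogeneous baselines). `forestconverge` treats neither as ground truth.
It computes each side's verdict independently and then classifies their
agreement, so that *disagreement itself becomes data*: a patch where a
stable canopy coexists with near-unanimous reports of decline is a
candidate for cryptic degradation, not a data error.

## Satellite verdict

### Transition accounting

Change detection is post-classification: two classified maps are
intersected pixel by pixel and the counts converted to areas. This assumes
the maps are co-registered, share one class scheme and one cell size, and
that classification errors are independent between epochs (the usual caveat
of post-classification comparison — misclassification at either epoch
creates phantom flows; an accuracy assessment of each input map is
therefore part of the pipeline, not an afterthought). Pixels nodata in
*either* epoch are dropped from both marginals, so class areas are
conserved along a chain of epochs over the common valid mask.

### Trend and the stability rule

The forest-area series of a patch is normalized to its baseline epoch
(100%), which puts patches of very different sizes on one axis and makes
the OLS slope interpretable as percent of baseline extent per year.
Ordinary least squares on calendar year is deliberately minimal: with at
most six epochs per patch there is no information to support
autocorrelation structure or changepoints.

The direction verdict uses two thresholds:

* `stable_max_net_change_pct = 2` — net change (percent of the window-start
  area, positive = loss) below which a patch can be called stable;
* `stable_min_trend_p = 0.10` — the slope p-value at or above which the
  trend is treated as flat.

Both must hold for "stable"; otherwise the sign of the net change decides
between decline and increase. Degenerate cases are resolved explicitly:
with only two epochs in the window the t-test has zero degrees of freedom,
the p-value is flagged undefined, and the rule degrades to the net-change
condition alone; a numerically perfect non-flat fit (zero residual
variance) is treated as significant; an exactly zero net change with a
significant trend falls back to the slope sign. The window defaults to
2010–2022 — chosen to overlap a ten-year survey recall period — and is
configurable.

### Reporting precision

All arithmetic is done at full precision; only reporting rounds, using
half-away-from-zero at one decimal place (two when the magnitude is below
0.1, so a 0.0856% loss reports as 0.09 rather than 0.1 or 0). R's
round-half-to-even would report 0.85 → 0.8 and silently disagree with
published tables.

## Survey verdict

Per-patch response proportions are computed over all respondents,
*including* "Don't know". The inclusive denominator is the convention under
which published directional shares (e.g. 46% increase / 35% decrease at
one site) need not sum to 100 across named categories. The consensus
direction is the modal directional category; ties give "none".

Association testing dispatches on the number of observed factor levels:
Fisher's exact test up to `level_cap = 4` levels, Kruskal–Wallis above.
The cap is a configurable judgment call — published analyses are not always
explicit about where "few levels" ends. Kruskal–Wallis needs an ordinal
response, so perceived change is rank-coded Decreased < No change <
Increased with "Don't know" excluded; the coding is a documented choice,
not canon. Fisher on tables larger than 2×2 attempts the exact network
algorithm first and falls back to a seeded Monte-Carlo p-value (10^5
draws) when the exact computation is infeasible, reporting which method
was used.

## Convergence classification

With m the share of responses matching the satellite direction
(decline ↔ Decreased, increase ↔ Increased, stable ↔ No change; "Don't
know" counts toward nothing) and o the largest non-matching directional
share, the decision precedence is: m ≥ 0.65 → full convergence; else
o ≥ 0.65 → dissonance; else partial convergence.

Two design points deserve the reasoning spelled out:

* **Inclusive thresholds.** A site where exactly 65% of respondents
  contradict a stable satellite signal classifies as dissonance. Strict
  inequalities would push boundary sites into partial convergence, which
  contradicts how such sites are handled in practice; comparisons are
  therefore `>=` and the thresholds are parameters of
  `threshold_config()`.
* **No fourth category.** A "weak / no convergence" outcome for matching
  shares below 0.35 is unreachable under this precedence: when no share
  reaches 0.65 the site is partial convergence regardless of how low m
  falls (such sites carry the mixed flag instead, defined as no
  *directional* category reaching 0.65). The matching proportion is
  recorded in every assessment so users can re-derive any alternative
  rule.
* **Recall period.** Ten-year recall is the default comparison horizon
  (matching a 2010–2022 analysis window); five-year is available by
  argument. For sites where the two periods differ in strength, both can
  be computed and reported.

## The synthetic-data generator

The generator exists so that every downstream stage has testable ground
truth despite the field data being restricted.

* **Landscapes.** The initial map is drawn by seeded region growing: one
  seed per `clump_size` pixels, each seed classed by the target
  proportions, then breadth-first accretion onto random assigned
  neighbours. This matches the target proportions in expectation while
  producing contiguous patches, so transition matrices have the spatial
  structure of real landscapes rather than salt-and-pepper noise. Later
  epochs apply an annual Markov kernel raised to the inter-epoch year gap
  (5, 5, 5, 2 years for a 2000–2022 design sampled at 2000, 2005, 2010,
  2015, 2020, 2022), independently per pixel. Per-pixel independence of
  *transitions* is a simplification: real clearance frontiers are
  spatially autocorrelated, so simulated change is more dispersed than
  real change at equal rates. Class frequencies nevertheless follow the
  chain P₀Kᵗ exactly in expectation, which is what the recovery tests
  verify.
* **Reflectance.** Band values are class-conditional Gaussians (SD 0.02,
  truncated to [0, 1]) with fixed means chosen to order NDVI(forest) >
  NDVI(shrubland) > NDVI(built-up) > NDVI(water) and give built-up
  surfaces positive NDBI. They emulate none of the atmospheric, phenological
  or sensor effects of real composites — sufficient for testing index code
  and ordering properties, not for training classifiers.
* **Surveys.** Respondent demographics come from marginal distributions
  (defaults: male-skewed, middle-aged, long-residency communities of a few
  hundred respondents, matching the scale of per-patch samples in
  multi-site studies). Responses are drawn from the target distribution
  with optional demographic effects added as log-odds shifts on the
  multinomial-logit scale — shifted probabilities therefore always remain
  a valid distribution, and no clipping is ever needed.
* **Determinism.** A single integer seed governs each scenario through one
  RNG stream (saved and restored around every simulation), and all file
  outputs avoid timestamps, so fixture bundles and pipeline outputs are
  byte-identical across reruns.

What passing tests on these synthetics shows: the accounting, trend,
dispatch and classification machinery is correct against independent
oracles and calibrated under a true null. What it does not show: robustness
to misregistration, classification error structure, recall bias, or
non-independent survey sampling — none of which the generator emulates.

## Numerical choices

* Normalized-difference denominators within 1e-12 of zero give nodata, not
  ±Inf; reflectances outside [0, 1] warn but compute.
* Probability vectors must sum to 1 within 1e-9.
* Largest-remainder apportionment in stratified sampling carries a floor
  of one sample per nonempty stratum; when the floors overshoot the total,
  the overshoot is removed from the smallest fractional remainders that
  remain above the floor.
* Accuracy metrics with a zero marginal are reported `NA` (undefined), not
  0; standard errors are binomial with each metric's own denominator.
  Estimators are simple (non-area-weighted) by design, matching how
  producer's/user's accuracies are typically reported alongside such
  studies; area-weighted estimators are out of scope.

## Problem sizes

The test-suite and acceptance computations use 128×128-pixel landscapes
(200 replicates for parameter recovery), a 200×200 landscape for the
closed-form Markov check, 500 replicate surveys of n = 300 for calibration,
map pairs up to 32×32 against the brute-force oracle, and all 44,515
2×2 contingency tables with n ≤ 30 against hypergeometric enumeration —
sizes at which the stochastic checks have tight expected behaviour while
the whole suite runs in minutes on one CPU.

## Known limitations

* Rasters are plain matrices with a text-grid interchange format; inputs
  must be co-registered and share a grid — no reprojection or resampling.
* National-scale rate aggregation is not implemented: published annual
  national deforestation rates depend on a rate formula and baseline areas
  that are rarely stated, so patch-level analysis is the supported scope.
* Survey ingestion expects pre-coded categorical responses and drivers; no
  free-text processing.
* The pipeline classifies agreement; it does not adjudicate it. Follow-up
  with high-resolution imagery or fieldwork is the intended next step for
  dissonant sites.
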