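---
title: "Presence-only maximum-entropy niche models and their transfer: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Presence-only maximum-entropy niche models and their transfer: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichemax)
```

## The modelling problem

`nichemax` models *climatic suitability* for a species from presence-only
information: instead of verified occurrence records, points are sampled at
random from a mapped geographic range ("pseudo-presences") and related to
climate. The scientific question the package is built around is a transfer
question: when a model trained on a species' native range is projected onto
another continent (or another time), how do the training-range choice
(modern vs historical range), the threshold rule, and non-analog climate
affect the prediction?

Two violations of the usual niche-equilibrium assumptions drive the design:

1. **Contracted modern ranges.** Many large mammals have lost range for
   non-climatic reasons (hunting, land use), typically at one climatic edge.
   A model trained on the contracted range learns a truncated niche. The
   package therefore treats the training period (modern or historical range
   mask) as an explicit experimental factor, with the modern mask required
   to nest inside the historical one.
2. **Non-analog climate in the projection region.** The transfer continent
   can hold climate combinations absent from the native continent. The
   package handles this by *clamping* (clipping projected predictor values
   to the training range) and reports per-cell *novelty* — the count of
   predictors outside the training envelope — so clamped cells are never
   silently interpreted as ordinary predictions.

## The maximum-entropy model

Let $x$ index background cells (a sample of the available environments of
the training region) and $f(x)$ a vector of features built from the
bioclimatic predictors. The model is the Gibbs distribution

$$ q_\lambda(x) = \frac{e^{\lambda \cdot f(x)}}{Z_\lambda}, \qquad
   Z_\lambda = \sum_{x \in \text{background}} e^{\lambda \cdot f(x)}, $$

the maximum-entropy distribution over the background subject to (relaxed)
constraints that the expected feature values under $q_\lambda$ match their
empirical means over the presences. Fitting maximizes the mean penalized
presence log-likelihood

$$ \frac{1}{m_p}\sum_{i} \left(\lambda \cdot f(x_i) - \log Z_\lambda\right)
   \; - \; \sum_j \beta_j |\lambda_j|, \qquad
   \beta_j = \beta \, \frac{s_j}{\sqrt{m_p}}, $$

where $m_p$ is the number of presences, $s_j$ the presence standard
deviation of feature $j$, and $\beta$ the single regularization multiplier
(default 1). The Karush–Kuhn–Tucker conditions of this convex problem give
the interpretable constraint-slack guarantee that the package asserts after
every fit: $|E_q[f_j] - \bar f_j| \le \beta_j$, with exact matching at
$\beta = 0$.

**Features.** Linear, quadratic and pairwise-product features of the
predictors, each predictor first standardized to $[0,1]$ by its training
min/max. Hinge and threshold features are deliberately out of scope: the
smooth feature set keeps the objective amenable to exact independent
verification (a derivative-free optimizer reproduces the fit to $10^{-8}$
in objective in the test suite), and the feature classes are a config field
so richer sets can be added later. The training min/max double as the clamp
bounds used during projection.

**Optimizer.** Cyclic coordinate-wise proximal Newton steps with
soft-thresholding for the L1 term and monotone step halving, followed by an
L-BFGS-B polish on the active set with signs fixed, iterated with KKT checks
on the inactive features. The trajectory is deterministic; the penalized
objective is non-increasing along it (asserted in tests). Convergence is
declared at a relative objective improvement below $10^{-8}$ per sweep or at
500 sweeps; a fit that hits the cap with a KKT residual above $10^{-6}$ is
returned flagged, with a warning.

Exactly duplicated feature columns are fitted as a single representative and
the coefficient (and any credited objective gain) is split evenly across the
duplicates. This leaves the objective value unchanged — within a duplicate
group the penalty is identical — and makes tie-breaking symmetric and
reproducible, so two predictors carrying identical columns report equal
contributions rather than an order artifact.

**Outputs.** The *raw* output is $q_\lambda$, normalized to sum to 1 over
the background. The *logistic* output is
$e^{H} q / (1 + e^{H} q)$ with $H$ the entropy of the fitted distribution;
this strictly increasing transform anchors the uniform model at exactly 0.5,
so 0.5 reads as "suitability of a typical presence environment". Percent
variable contributions are path attributions of the optimizer's objective
increments to the source predictors of each updated feature (product
features split evenly); because any path attribution is heuristic, the test
suite validates it only by rank agreement with drop-one refits, and a
single-variable jackknife (each predictor fitted alone, scored by test AUC)
is provided as the model-free complement.

## Bioclimatic predictors

`derive_bioclim()` computes the ten classical predictors from monthly
minimum/maximum temperature and precipitation: MTEMP, TEMPR, ISO, TEMPS,
MTWM, MTCM, PREC, PRECS, PWQ, PDQ. Three conventions matter and are easy to
get silently wrong:

- **Scales.** ISO is the plain ratio (mean monthly range / annual range) in
  $(0, 1]$, and TEMPS is the standard deviation of monthly mean temperature
  in °C. Some distributed climate products store these ×100 as packed
  integers; that packing is a storage artifact and is *not* used here.
  Envelope plots and clamp bounds depend on this choice.
- **Quarters** are the twelve wrap-around consecutive three-month windows,
  so December–January–February is a candidate quarter.
- **Population SD** (divisor $n$) is used for TEMPS and PRECS: the twelve
  months are the full population of months, not a sample from one.

Aggregation to coarser grids (`aggregate_grid()`) is the block mean,
ignoring nodata, with ragged edge blocks averaging the cells available —
appropriate for interpolated climate surfaces, not for categorical layers.

## Sampling design

Pseudo-presences are drawn uniformly over the occupied cells of a range
mask and placed at cell centers. Predictors are cell-constant, so sub-cell
jitter would add no information while breaking exact reproducibility.
Sampling is uniform over cells rather than area-weighted by latitude,
matching the planar-GIS sampling practice the procedure emulates; on the
synthetic planar landscapes the two coincide. The default layout is ten
replicate sets of 100 training points and 100 test points per species and
period. Every draw derives its stream from
`hash(master_seed, species, period, role, set_index)`, so replicates are
independent and reproducible regardless of execution order.

Thresholds follow the two standard criteria, applied per replicate run and
then combined by cell-wise union ("cumulative" maps): MTP, the minimum
logistic score among the run's training presences (generous, zero training
omission), and MTSS, the score maximizing training sensitivity plus
specificity (stringent). MTSS is computed from the training presences
against the run's background sample by default — the held-out
presence/absence test points are reserved for Cohen's kappa — with a switch
(`mtss_reference = "absence"`) for the alternative. Ties use the $\ge$
rule everywhere, and MTSS tie-breaks to the smallest maximizing threshold.
One nomenclature warning: part of the evaluation literature labels the
"proportion of specific agreement" as kappa; what this package computes is
Cohen's chance-corrected kappa, stated explicitly in the docs.

Test AUC follows the convention of scoring test presences against the
background sample; pseudo-absence references are equally supported and used
for the kappa-based threshold evaluation.

## The synthetic landscape generator

Real inputs (interpolated climate rasters, published range maps) are
external downloads, so the generator is a first-class module that creates
landscapes with the statistical structure the analysis assumes and with
known truth:

- **Climate.** One raster, two disjoint rectangular continents (64×64 cells
  each by default) separated by a nodata sea gap. Temperature has a
  north–south gradient (10–28 °C annual mean on the native continent) with
  a seasonal sinusoid whose amplitude grows poleward (2–12 °C) and a
  positive monthly temperature range; precipitation declines linearly
  west-to-east (continentality) with a wet-season phase. All noise fields
  are smoothed Gaussians (kernel width 3 cells). Temperature varying with
  latitude and moisture with longitude keeps the two main gradients
  near-orthogonal — like a continent with a maritime west coast — which
  also makes the two-driver truth statistically identifiable for the
  recovery experiments; the noise amplitudes (1 °C, 6 mm/month) are kept
  moderate so min/max standardization is not dominated by single extreme
  cells. The transfer continent is 4 °C colder, 30% more seasonal and 10%
  drier: a cooler, more continental target whose cold end is non-analog,
  the geometry of projecting a warm-origin species onto a temperate
  continent.
- **Truth.** Suitability is a known Gibbs density over the standardized
  predictors, by default $\lambda^* = (\text{MTEMP: } 3, \text{PREC: } 2)$ —
  a warm-wet niche with linear terms only, so fitted linear weights are
  directly comparable to $\lambda^*$ without identifiability issues from
  quadratics. The historical range is the top 20% of native cells by true
  suitability (ties, which arise only for the all-zero null truth, broken by
  a seeded random order); the modern range removes 50% of it, by default
  the *coldest* occupied cells — the biased contraction mechanism under
  study. A handful of "introduction" cells on the transfer continent with
  true suitability above the occupancy threshold emulate naturalized
  populations outside the native range; because the transfer continent is
  colder, these sit near the cold edge of the native climatic envelope,
  which is exactly what makes them diagnostic for threshold behaviour.
- **Null scenarios.** All-zero weights give a uniform truth and a random
  range. Note that a true null requires a null contraction as well:
  cold-edge contraction of even a random range manufactures a warm-biased
  modern mask, which is signal, not noise. The null calibration therefore
  pairs zero weights with `contraction = list(fraction = 0, bias = "random")`.

What the generator does *not* emulate: dispersal limitation and biotic
interactions, temporally changing climate, realistic circulation-driven
climate fields, and observation error in the range maps. Passing tests on
these landscapes therefore demonstrate the correctness and the qualitative
mechanisms of the procedure — truncated-niche underprediction, threshold
behaviour at the envelope edge — not predictive skill on any real species.

## Numerical choices and degenerate inputs

- Cell membership is half-open ($x \in [x_l, x_r)$, $y \in (y_b, y_t]$), so
  points on shared edges resolve uniquely; the grid's own top edge belongs
  to row 1.
- Predictors constant on the training data are dropped (warning) together
  with their features; an all-constant table is an error.
- ISO is nodata where the annual temperature range is zero (logged).
- PRECS is defined as 0 where mean precipitation is 0.
- Chance-agreement kappa ($p_e = 1$) returns 0.
- Empty score vectors, empty sampling pools, misaligned grids and
  out-of-extent points are hard errors naming the offender; points on
  nodata cells are excluded with logged counts.
- ESRI ASCII is the interchange raster format (GeoTIFF would need GDAL
  bindings, which the package deliberately does not depend on); values
  round-trip at double-precision text accuracy.

## Problem sizes used in the shipped experiments

The shipped tests and the acceptance script run entirely on synthetic
scenarios: 64×64 cells per continent for the replicate experiments
(10 runs × 100 points, full background), 100×100 with 1,000 truth-drawn
presences over 10,000 background cells for parameter recovery, and
24×24 or smaller for unit-level checks. These sizes were chosen so the full
pipeline stays comfortably interactive while keeping every estimate's
sampling error well inside the tolerances being asserted; the multi-seed
sweeps use 10 scenario replicates, and the null calibration uses 3 model
runs per seed.

## Known limitations

- Percent contribution is path-dependent by construction; use the jackknife
  for a model-free importance ranking.
- Hinge/threshold/categorical features, bias-corrected background sampling,
  multivariate novelty surfaces (MESS-style) and reprojection are out of
  scope, as are the cumulative-percentile output format and any attempt to
  reproduce a specific software implementation bit-for-bit.
- The logistic transform's 0.5 anchor is a convention, not a calibrated
  probability of presence; only orderings and threshold-based summaries are
  interpreted.
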