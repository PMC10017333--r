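---
title: "Methods: UAV multispectral phenotyping and genetic evaluation of slash pine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: UAV multispectral phenotyping and genetic evaluation of slash pine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`pinephenomics` implements a complete drone-based phenotyping and genetic
evaluation workflow for a slash pine (*Pinus elliottii*) open-pollinated
progeny trial: from surface/terrain/band rasters to individual tree crowns,
from crown spectra to machine-learning predictions of needle nitrogen (N)
and nonstructural carbohydrate (NSC) content, and from monthly predicted
traits to REML variance components, narrow-sense heritability and family
breeding values. Because trial imagery and needle chemistry of this kind
are rarely public, the package ships a first-class synthetic-orchard
generator that encodes the statistical structure the analysis assumes; all
tests and the acceptance script run on generated data.

## The trial and its generator

The emulated design is a two-site trial, 20 incomplete blocks per site,
each block holding one tree of each of 20 open-pollinated families
(single-tree plots, 2 m within rows, 3 m between rows): 800 trees. The
generator randomises family positions within each block with a seeded
permutation — a deliberate simplification of alpha-lattice randomisation
that preserves what the variance analysis relies on (every family once per
block, blocks nested in sites).

Monthly trait values follow the same mixed model the estimation stage
assumes:

y_ijkm = mu_m + site_i + block_ij + family_k + e_ijkm,

with block ~ N(0, s2_b), family ~ N(0, s2_f), e ~ N(0, s2_e). Family
effects are drawn once and held constant across months by default (one
genetic value per family; months differ through their means and residuals),
since each month's trait is analysed as a separate realisation. A
`redraw_monthly` mode redraws family effects per month for studying
month-varying heritability, and `family_set`/`family_shift` plant known
superior families for recovery experiments. Planted-signal recovery sets
effects *exactly* (e.g. at one phenotypic SD) rather than adding a shift to
random draws: a recovery experiment must control its ground truth, or
failures conflate the method with the luck of the draw.

Default components give true narrow-sense heritabilities near the values
the monthly analysis is designed to resolve: for N, s2_f = 0.010,
s2_b = 0.010, s2_e = 0.080 (trait in percent dry mass, h2 = 0.25); for NSC,
s2_f = 0.15, s2_b = 0.10, s2_e = 1.20 (h2 = 0.26). Monthly means follow
conifer needle phenology (N peaking with the spring flush, NSC declining
through the growing season and recovering after growth cessation), with N
around 1.3–1.9 % and NSC around 7–12 %. Values are clipped to plausibility
bounds (N within 0.5–4 %, NSC within 5–15 %) and the clip count recorded.

The eleven flight months are January and March–December — February is
absent from the acquisition calendar — so every "monthly" loop in the
package runs over 11 labels.

### Trait-to-reflectance forward model

No mechanistic statement links needle chemistry to canopy reflectance here;
the forward model is an artifact convention chosen so the learning stage
has signal to find. Each band is baseline + c_N·N + c_NSC·NSC + Gaussian
noise, clipped to [0, 1]. Default coefficients follow the qualitative
physiology — more N (chlorophyll) darkens the visible bands and brightens
red-edge/NIR — while NSC carries a weaker signature concentrated in green
and red-edge, deliberately near-orthogonal to the N direction: rank 2 alone
is not enough, because nearly collinear coefficient vectors make the two
traits formally identifiable but practically inseparable (their predictions
become mirror images, and bivariate selection on predictions degenerates).
`optics_config()` therefore warns when the directions' |cosine| exceeds
0.95. Band noise SD defaults to 0.01 reflectance units, a modest
sensor/BRDF proxy.
This linearity is exactly what PLSR can exploit; the interesting
comparisons are therefore *relative* (overfitting gaps, noise trends), not
absolute accuracies, which on real canopies would be lower and
method-ranked differently.

### Scene rendering

Rendered rasters mimic what photogrammetric processing delivers: a smooth
analytic terrain (base 100 m plus two sinusoids, total relief under 10 m,
matching a near-flat plantation), a surface model compositing one right
circular cone per tree (apex at true height, base radius = crown radius,
cellwise maximum), and five band layers painting each crown disc with the
tree's reflectance over a soil background darker in NIR than any canopy, so
NDVI separates crown from ground. Overlapping crown pixels belong to the
nearest apex. The grid uses a top-left origin with square pixels and is
aligned half a pixel off the planting grid so every planted position falls
on a pixel centre — cone apexes are sampled exactly, which makes
apex-recovery assertions sharp instead of one-pixel-fuzzy. Rasters are
written as 32-bit-float TIFF with ESRI world files plus JSON sidecars
carrying value offset/scale (floats are stored scaled to [0, 1]), nodata
and the frame tag; elevation quantisation after a disk round trip is about
1e-5 m over a 120 m range.

## Canopy image analysis

CHM = DSM − DTM, cellwise; nodata propagates and negative cells (surface
reconstruction noise in real data) are clamped to zero with a logged count.

Detection is a variable-window local-maxima filter: a cell is an apex iff
its height is at least the 2.6 m floor and it is the strict maximum within
a circular window of radius clamp(a + b·height, r_min, D_max/2), with
defaults a = 0, b = 0.3 m per metre of height, r_min = 0.5 m and
D_max = 2.5 m (the floor and crown cap the field protocol uses; the linear
clamped radius rule is the package's choice, exposed in config, since only
the cap is prescribed). Ties break to the first cell in row-major order;
candidates closer than r_min merge keeping the taller. The kernel refuses
resolutions at which r_min spans less than one pixel.

Crown delineation is classic CHM region growing: apexes processed
tallest-first, each crown admitting 4-connected neighbours whose height
exceeds both 45 % of the apex height and 55 % of the current crown's mean
height, never farther than D_max/2 from the apex, never into a claimed cell
(first claim wins). The 0.45/0.55 thresholds are the conventional defaults
of this algorithm family. One geometric consequence worth stating: on an
ideal cone the admissible region ends where the cone drops below 45 % of
the apex, i.e. at 55 % of the true crown radius, so delineated synthetic
crowns are systematically narrower than rendered ones — tests assert
against this derived value, not against the rendered radius. Crown spectra
are means over footprint pixels (median and shade handling are out of
scope), and crowns are matched to planted positions by greedy
nearest-neighbour under a 1 m tolerance.

Both kernels are C++ (Rcpp): the inner loops visit millions of cells at
5 cm resolution, which pure R would not do within a practical test budget.

## Spectral features

Sixteen vegetation indices are computed from the five bands (Blue 450,
Green 560, Red 650, Red-edge 730, NIR 840 nm) and appended to them for a
21-variable predictor set. Two formulas are implemented exactly as adopted
by the workflow even though they deviate from common literature forms — EVI
without the usual 2.5 gain, and MNLI with the green band where most
formulations use red — and the catalogue (`vi_catalog()`) annotates both.
NRI and GRVI share one formula, (G − R)/(G + R); both columns are kept
because the feature set ranks them separately. Zero denominators flag the
row for downstream exclusion rather than imputing or silently propagating
NaN.

## Trait prediction models

The pooled 11-month table of ground-sampled tree-months is split once into
80 % calibration / 20 % validation (calibration = floor(0.8 n); 383 rows
give 306/77). Four families are compared under one protocol: predictors
standardised by calibration statistics only; hyperparameters searched by CV
entirely inside the calibration set; validation rows touched exactly once.

* **PLSR** — NIPALS partial least squares (mixOmics engine), up to 10
  components, chosen by leave-one-out CV.
* **SVM** — radial kernel (e1071), grid over cost {0.25, 0.5, 1, 2, 4} and
  kernel width {0.01, 0.1, 1}, 5-fold CV.
* **GBM** — gradient boosting (xgboost engine), depth 3, grid over learning
  rate {0.01, 0.05, 0.1} and tree count {100, 300, 500, 1000}, 5-fold CV.
* **RF** — randomForest with 300 trees, no grid (tree count is the
  parameter that matters and is fixed by protocol).

R² is defined as 1 − SS_res/SS_tot about the evaluated dataset's own mean —
not a squared correlation — so held-out values can be negative; RMSE is in
trait percent units. Variable importance is permutation-based for every
family (mean RMSE increase over 10 seeded permutations per predictor,
negatives clamped, rescaled to max 100): a single definition keeps scores
comparable across methods, which method-native importances are not. For
PLSR the held-out 20 % metrics are reported like every other method; LOO
serves only to pick the component count.

## Genetic evaluation

Variance components are estimated by REML under the model above (fixed:
intercept + site; random: block, family, residual). The implementation
profiles out the residual variance and maximises the restricted likelihood
over the two variance ratios on the log scale, with all linear algebra on
q×q cross-products (q = blocks + families, 60 at trial scale) via the
Woodbury identity — a fit at n = 800 takes milliseconds, which the
repeated-seed recovery studies rely on. Numerical choices: L-BFGS-B from
three starts on log-ratios bounded in [−16, 8]; explicit boundary profiles
with either or both ratios pinned at zero; ratios below 1e-7 snapped to the
boundary and the remaining ratio refitted; the exact restricted
log-likelihood (including its constant) is exposed as `reml_loglik()` for
validation, and matches both a dense-matrix oracle and lme4 to printed
precision in the tests.

Heritability is h² = 2.5 s2_f / (s2_f + s2_b + s2_e): open-pollinated
families are treated as a bit more related than half-sibs (2.5 rather than
4 as the additive conversion). The coefficient admits h² > 1, which is
reported with a warning, not truncated; it is overridable but not by
default. Family breeding values are a_i = h² (ȳ_i − μ̂) with μ̂ the grand
mean of the trait for that month. Bivariate selection applies the
first-quadrant rule: families whose breeding values exceed the
across-family mean for *both* traits in *every* month of the chosen set
(late season, July–October, by default), ranked by summed standardised
breeding values. The underlying bivariate REML (genetic covariance between
traits) is deliberately out of scope; selection composes the univariate
fits.

## What passing tests do and do not show

The generator matches the estimator's assumptions exactly: Gaussian,
balanced, independent effects, linear optics, cone crowns on smooth
terrain. Passing recovery tests therefore demonstrates correctness of the
implementation under its own model, and nothing about robustness to the
things real trials add — spatial autocorrelation, G×E across years,
non-Gaussian residuals, crown asymmetry and mutual shading, BRDF and
illumination drift, matching errors from RTK drift. The detection
precision/recall of ~1.0 on rendered cones is a property of clean cones at
5 cm pixels, not a field expectation.

## Problem sizes and seeds

The test suite runs the full trial scale (800 trees) where the property
needs it — heritability recovery (50 seeded trials, interior truth and
boundary truth), planted-family selection recovery (50 seeds), detection
fidelity at 5 cm pixels — and reduced layouts (1–2 sites, 3–5 blocks, 10 cm
pixels, 2–3 months) for end-to-end pipeline properties such as byte-level
determinism and checkpoint consistency, keeping the default run to a few
minutes. The analysis scripts use the full layout at 10 cm pixels over all
11 months. Every stochastic stage is a pure function of (config, seed);
pipeline stage seeds derive from one master seed by a documented string
hash, so whole runs are byte-identical under one seed.

## Known limitations

* The univariate-per-trait-month model ignores genetic covariance between N
  and NSC; the quadrant rule approximates what a bivariate index selection
  would do.
* Individual-tree BLUP is not implemented; breeding values are family-mean
  shrinkage estimates.
* Crown polygons are convex hulls of pixel footprints — adequate for area
  and matching, not for concave crown shapes.
* The forward optics model is linear and month-independent; no
  radiative-transfer realism is attempted or claimed.
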