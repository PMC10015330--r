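---
title: "Quantifying skeletal pneumaticity: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying skeletal pneumaticity: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pneumaticity)
```

## The problem

Most birds carry air inside some of their bones: post-hatching, epithelial
diverticula of the air-sac system invade the skeleton and replace marrow
with air. The humerus is the long bone most often pneumatized. Given a
microCT scan of a fresh specimen, the extent of pneumatization of a single
element can be measured directly, as the volumes of bone, marrow and air it
contains, and those volumes support three kinds of questions:

1. **How pneumatized is the element?** Air space proportions,
   `ASP_i = V_air / (V_air + V_marrow)` (internal cavity) and
   `ASP_t = V_air / (V_air + V_marrow + V_bone)` (whole element).
   Distinguishing the two matters: treating the whole endocast as air, as
   skeleton-based studies must, systematically overestimates pneumaticity
   whenever marrow persists in the cavity.
2. **How heavy is it?** Bulk density from the volume triple under assumed
   tissue densities (bone 2.05 g cm⁻³, marrow 1.0 g cm⁻³, air massless).
3. **What explains variation across species?** Phylogenetic regressions of
   log air volume and log bone volume on log internal-cavity volume, log
   body mass, and diving/pneumaticity indicators, compared by AICc.

This package implements that chain end to end, and ships a synthetic-data
generator so each stage is testable against known truth without scan data.

## Voxel volumetrics

Segmentation is plain grey-value thresholding, reflecting the density
ordering air < marrow < bone in CT: inside a caller-supplied mask, a voxel
with grey `g` is air when `g < t_am`, marrow when `t_am <= g < t_mb`, bone
when `g >= t_mb`. The intervals are half-open with the denser tissue
winning at a boundary — an arbitrary but deterministic and testable
convention. Volumes are voxel counts times `voxel_size^3`. Only isotropic
voxels are accepted, since a scan has a single stated resolution. No
connected-component cleaning or smoothing is applied by default; an
optional 7-point median pre-filter (`median_filter = TRUE` in
`segment_grid()`) can suppress isolated speckle, but plain thresholding is
the reference behaviour.

Scan adequacy is summarized by the ratio of element diameter to voxel
size (`resolution_ratio()`); the quality flag passes at ratio ≥ 22, the
lower end of what whole-specimen microCT of bird humeri typically achieves
(roughly 22–121).

**Accuracy.** The digital phantom (hollow cylinder, analytic volumes)
shows the discretization error of centre-point voxel classification: at 50
voxels across the diameter the total-volume error is below 1%, at 100
voxels below ~0.1%. ASP estimates are more accurate still because
numerator and denominator errors partially cancel.

## Pneumaticity metrics

* `ASP_i` is undefined for a solid element (no internal cavity) and
  returns `NA`; such elements are excluded from ASP summaries but retained
  for density and bone-fraction summaries, because near-solid elements
  (penguin-like, bone fraction above 90%) are biologically real.
* An element is *pneumatic* when `ASP_i > epsilon` with `epsilon = 0.001`
  by default (strict inequality). A strictly positive threshold absorbs
  segmentation speckle in real scans; it is configurable.
* Species averaging is nested and unweighted: left/right humeri average
  within a specimen, specimen means average within a species. Flat pooling
  of humeri was rejected because it over-weights specimens with two
  scanned sides. Derived metrics are computed on species-mean volumes by
  default; `metrics_on = "elements"` averages per-element metrics instead,
  since published practice does not always state which is meant.
* Bulk density: mass = 0.001·(2.05·V_bone + 1.0·V_marrow) g with volumes
  in mm³, density = mass / (0.001·V_total) g cm⁻³. Pure bone gives
  2.05 exactly, pure marrow 1.0; replacing marrow by air at fixed bone and
  total volume strictly lowers density.

## Phylogenetic regression

The comparative engine is GLS with the error covariance proportional to
the λ-transformed Brownian-motion matrix of an ultrametric time-scaled
tree: `e ~ N(0, σ² C(λ))`, `C[i,j]` the shared root-to-MRCA path length,
`C(λ)` multiplying off-diagonals by λ. Estimation choices:

* **β̂** `= (XᵀC⁻¹X)⁻¹XᵀC⁻¹y` via Cholesky whitening and QR, with a hard
  error naming aliased columns when the whitened design is rank deficient.
* **σ̂²** is the ML estimate `eᵀC⁻¹e / n`; the log-likelihood is
  `-(n/2)·log(2πσ̂²) - ½log|C| - n/2`. Standard errors, t and p values use
  the `n/(n−p)` small-sample variance correction with `n−p` degrees of
  freedom — the common PGLS convention — while the likelihood stays
  ML-consistent for AICc.
* **λ̂** maximizes the profile likelihood over [0, 1]: a 21-point grid
  seeds a bounded golden-section search (tolerance 1e-8), and both
  endpoints are compared explicitly because boundary estimates (λ̂ = 0
  exactly) are common in real analyses. λ is optimized per model, not
  shared across a family. A perfect fit (σ̂² = 0) short-circuits the
  search and reports `logLik = Inf` rather than failing.
* **AICc** `= −2logL + 2k + 2k(k+1)/(n−k−1)` with
  `k = #β + 1 (σ²) + 1 if λ estimated`. Because the parameter-count
  convention differs between software packages, cross-software comparisons
  should use Akaike weights or coefficients, which are convention-free.
* **R²** `= 1 − eᵀC⁻¹e / e₀ᵀC⁻¹e₀` against the intercept-only GLS under
  the same λ̂.
* Logical predictors are coded 0/1 with coefficients named `<var>_TRUE`;
  species matching between table and tree is case-sensitive after
  space/underscore normalization, and mismatches are hard errors, never
  silent drops.

Two exact reductions anchor the implementation against independent
oracles: at λ = 0 on an ultrametric tree the fit equals OLS, and at λ = 1
the slope equals the phylogenetically-independent-contrasts through-origin
regression slope. The test suite checks both, plus agreement of λ̂,
coefficients and log-likelihood with `nlme::gls` + `ape::corPagel`.

`compare_models()` fits a family on the single complete-case species set
across the union of all variables (so AICc values are comparable), ranks
by AICc, and flags models whose Akaike weight falls below 1/8 of the best
model's as negligible. The **bone thickness index** (BTI) is the residual
vector of the null scaling model `bone ~ internal` under ML λ: positive
values mean relatively thick cortical bone for the element's size. GLS
residuals are centred in the `C⁻¹` inner product, so BTI values average
to zero in that metric, not arithmetically.

## The synthetic-data generator

The generator emulates the study design, not real humeral anatomy.

* **Trees** are pure-birth (Yule) simulations rescaled to a fixed
  100 Myr depth, so rate-like parameters are comparable across tip
  counts; only tree shape matters for PGLS behaviour. No attempt is made
  to mimic any real topology or calibration.
* **Predictor traits** — log10 internal cavity volume (root 3, i.e.
  ~1000 mm³) and log10 body mass (root 2.2, plus independent noise of
  s.d. 0.3) — evolve by Brownian motion with rate `sigma2` (default 0.005
  per Myr, giving a realistic ~0.7 decade spread at the tips). Their
  correlation arises only through shared phylogeny, the simplest structure
  sufficient for effect-recovery tests.
* **Flags** (diving, pneumaticity) are i.i.d. Bernoulli at the tips
  (defaults 0.2 and 0.65, the observed cohort frequencies), which keeps
  design matrices full rank at small n; `clustered_flags = TRUE` flips
  whole clades instead, for studying phylogenetically clumped ecology.
* **Responses**: log bone volume is
  `0.434 + 0.5·internal + 0.428·mass + 0.174·diving − 0.193·pneumatic`
  plus residual noise; log air volume (pneumatic tips only) is
  `−0.27 + 1.044·internal` plus noise. These defaults are the
  best-supported empirical estimates for the avian humerus, so a default
  synthetic cohort reproduces the study conditions: ~74% mean ASP_i,
  bulk densities near 1.0 (pneumatic) and 1.7 g cm⁻³ (apneumatic),
  weak positive allometry of air volume, weak negative allometry of
  bone volume.
* **Residual noise** has covariance `noise_sd² · Λ(C/depth, λ_true)`:
  the tip-level residual s.d. is exactly `noise_sd` (default 0.05 on the
  log10 scale) for every λ, and `λ_true` controls only the cross-tip
  correlation. Keeping the tip scale fixed separates "how noisy" from
  "how phylogenetically structured", which makes both coefficient
  recovery and λ recovery cleanly testable; `sigma2` concerns the
  predictors only.
* **Phantoms** are hollow cylinders (cortical shell, air proximally,
  marrow distally) with closed-form true volumes. They deliberately omit
  epiphyses, pneumatic foramina and trabecular structure: they oracle the
  *measurement* chain, not the anatomy.

What passing tests on synthetic data do **not** show: robustness to
beam-hardening and grey-value drift, partial-volume effects at real
tissue interfaces, operator-dependent masks, phylogenetically clumped
ecology (under the i.i.d. default), or errors in body-mass compilations.

## Pipeline conventions

`run_pipeline()` is deterministic given config + seed, logs every filter
with before/after counts, and never drops a species silently. The
air-volume family is fitted on pneumatic species minus an explicit,
configurable exclusion list (real datasets sometimes exclude a few
marginal specimens, and the subset rule used is always logged); it is
skipped with a logged reason when fewer than five species carry air,
mirroring the situation where diving effects on air volume are
unanalysable because almost no diver is pneumatized. Models whose
categorical predictors are constant in the fitting subset are dropped
from the family with a log line rather than failing the run. Outputs are
species metrics, long-format model tables (model, n, AICc, weight, R²,
λ, term, estimate, s.e., t, p), BTI per species, a summary report
(ASP to the whole percent, densities and BTI to 2 d.p.) and a
provenance block (config hash, package version, seed).

## Problem sizes and numerical tolerances

The test suite simulates at the scales the questions require while
staying lightweight: oracle-equivalence checks use 20 random instances
(trees to 32 tips); coefficient recovery uses 100 replicates of
150-tip cohorts; λ recovery uses 40 replicates per λ ∈ {0, 0.5, 1};
phantom accuracy uses 50–100 voxels across the diameter. λ optimization
tolerance is 1e-8; OLS equivalence is asserted to 1e-8, contrasts
equivalence to 1e-6; Cholesky factorization failure of a covariance
matrix is a hard conditioning error.

## Known limitations

* Segmentation is global-threshold only; no per-region adaptive
  thresholds, no Hounsfield calibration, no mesh-based volumetrics.
* Marrow composition (fat vs haematopoietic) is ignored; marrow density
  is a single constant.
* Only Pagel's λ is implemented; κ, δ, OU processes and
  measurement-error PGLS are out of scope, as are ancestral-state
  reconstruction and plotting of tree figures.
* Body mass enters as a species-level constant; sex dimorphism is not
  modelled.
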