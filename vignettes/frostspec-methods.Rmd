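---
title: "Methods: index construction, spectral modeling and the synthetic testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: index construction, spectral modeling and the synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frostspec)
```

## The problem

Freezing injury in tea (*Camellia sinensis*) is conventionally quantified by
destructive assays of leaf physiology: relative chlorophyll content (SPAD),
soluble sugar (SS), malondialdehyde (MDA), and the antioxidant enzymes
catalase (CAT), peroxidase (POD) and superoxide dismutase (SOD). frostspec
implements two linked analyses:

1. a **Low Temperature Response Index (LTRI)** that condenses the six
   markers into one severity score via a principal-component coefficient
   chain, and
2. a **chemometric pipeline** that predicts the index (or any single
   marker) from leaf reflectance spectra in the 397–1008 nm range (176
   channels, ~3.5 nm steps), through preprocessing, wavelength selection
   and a grid of regression models.

No public dataset accompanies the original study, so the package also
ships a synthetic-data generator that emulates the experimental design
(2 cultivars × 6 cold treatments × 16 plants = 192 samples) with planted
ground truth, and all empirical guarantees are phrased as properties of
that generator.

## The index chain

The six markers are standardized column-wise (z-scores, n−1 denominator)
and decomposed by PCA on the correlation matrix. Loadings are reported on
the correlation scale (eigenvector × √λ), so eigenvalues sum to p and each
loading column has squared norm λ. Components with λ > 1 are retained
(Kaiser rule). The chain then computes, per retained component j and
marker i:

* linear combination coefficients `LCC_ij = LC_ij / sqrt(λ_j)` — the unit
  eigenvector entries;
* composite coefficients `CSC_i = Σ_j LCC_ij · VC_j / CVC_m`, the
  variance-contribution-weighted average over retained components;
* normalized weights `w_i = CSC_i / Σ_k |CSC_k|`, a sign-preserving
  "percentage" normalization so that absolute weights sum to one.

A sample's LTRI is `Σ_i w_i z_i` on the standardization of the fitting
panel; lower values mean more severe cold damage.

Two typesetting issues in the source material deserve note. The formula
for the combination coefficients is sometimes printed as a division by λ
rather than √λ, but only the √λ form reproduces the published coefficient
equations (0.826/√2.862 = 0.488), so frostspec implements √λ. Likewise one
printed first-component entry (−0.322 for CAT) is inconsistent with its
own loading (−0.562/√2.862 = −0.332); the package follows the arithmetic,
which is also the value that propagates correctly to the published
composite coefficient (−0.398). The reference tables ship as a plain-CSV
fixture (`ltri_reference()`), and the full chain reproduces all published
coefficients to ±0.001:

```{r}
ref <- ltri_reference()
lcc <- linear_combination_coefficients(ref$loadings, ref$variance$eigenvalue[1:2])
csc <- composite_coefficients(lcc, ref$variance$vc[1:2], ref$variance$cvc[2])
ltri_equation(round(normalize_coefficients(csc), 3))
```

Eigenvector signs are inherently arbitrary; frostspec fixes them by making
the largest-|loading| entry of each component positive, which matches the
sign pattern of the published tables.

## Spectral preprocessing

* **Reflectance correction** `C = (R − D)/(W − D)` against dark and white
  references; invariant to common affine rescaling of all three frames;
  optional clipping to [0, 1] behind an explicit flag (default off).
* **ROI extraction**: leaf pixels are segmented by thresholding the
  mean-over-bands intensity image (Otsu's method by default — the
  threshold value is not specified in the source protocol) and the
  per-band mean over the mask is the sample's spectrum.
* **MSC** regresses each spectrum on a reference (by default the mean of
  the processed set) and inverts the fitted affine map, removing exactly
  the gain/offset scatter class the generator plants; it is idempotent.
* **Savitzky–Golay** smoothing (window 11, order 2 by default; neither is
  stated in the source, both configurable) is delegated to
  `signal::sgolayfilt` and verified in the test suite against an explicit
  per-window least-squares oracle.
* **First derivative** is the forward difference divided by the wavelength
  step (mean axis spacing by default, ≈3.5 nm); the result lives on
  midpoint wavelengths and is one band shorter.

The combined chain order is MSC → S-G → derivative: scatter removal before
smoothing before differencing. The source describes the three pretreatments
as "combined" without an order; this order is the package's choice and each
stage can be disabled.

## Wavelength selection

* **SPA** grows chains of minimally collinear bands by successive
  orthogonal projection, from 20 random start bands (the "epochs"
  parameter of the source configuration is interpreted as the number of
  candidate starts), scoring every chain length from 1 to 30 by MLR RMSE
  on a held-out 30% split.
* **CARS** runs 300 Monte Carlo iterations; each fits a ≤10-component PLS
  on a random 80% calibration draw, weights bands by normalized
  |coefficient|, enforces an exponentially decreasing retention count
  calibrated so the first iteration keeps all bands and the last keeps 2,
  then resamples adaptively within the survivors. The subset with minimal
  10-fold CV RMSE wins.
* **UVE** appends as many uniform noise bands (scaled to 1e−10 of the mean
  signal) as real bands, collects leave-one-out PLS (5 components)
  coefficient vectors, computes reliability c = mean/sd per band, and
  retains real bands whose |c| exceeds the 0.99 quantile of the noise
  reliabilities. The quantile uses the (n+1)p plotting-position convention
  so that, under a null response, a real band exceeds the threshold with
  probability exactly 1 − cutoff. The "Leave-One-Out 700" entry of the
  source configuration is not interpretable at n = 192; plain LOO is used,
  and a Monte-Carlo resampling mode is available via `uve_mc_resamples`.

All three selectors are deterministic given their seed and return full
diagnostic traces. In the grid runner, selection is refit per
cross-validation repeat by default (leakage-safe); a `selection = "once"`
flag reproduces the simpler fit-once protocol.

## Regression families

PLS is implemented natively (NIPALS, centred, optionally autoscaled; for a
univariate response the inner loop has a closed-form fixpoint) because the
selectors need its coefficient vector. SVM (polynomial kernel, C = 1), RF
(200 trees, minimum leaf 5) and the BP network (one hidden layer of 32
units — width unspecified in the source) are backed by e1071,
randomForest and nnet respectively; nnet trains by quasi-Newton descent
rather than the source's plain gradient descent, with the epoch budget
mapped to `maxit`. The 1-D CNN (three same-padded kernel-3 convolutions of
16/32/64 channels, ReLU, one max-pool of 2, dropout 0.5, dense output) and
the LSTM (bands as a length-176 sequence of scalars, 20 hidden units,
dropout 0.5) are written in plain matrix algebra with Adam and are
verified against finite-difference gradients in development. Inputs to
both deep models are row-L2-normalized and the target is internally
standardized. Channel counts and kernel sizes are package defaults — the
source states only the layer structure — and every parameter can be
overridden per grid run.

A known limitation: at its published budget (40 epochs, learning rate
0.001) the LSTM is a weak learner on ~150-sample training sets; it
completes and is reproducible, but rarely competitive. No early stopping
is applied anywhere, mirroring the fixed-epoch protocol.

## Evaluation protocol

`make_cv_plan(192, 5)` partitions samples into four folds of 39 and one of
36; the four equal folds serve as evaluated repeats (test 39 / train 153)
and metrics are averaged over them — this reproduces the source's "repeated
4 times" arithmetic exactly. When n is divisible by k all folds are
evaluated. Metrics are R² = 1 − SSE/SST (mean over the evaluated set),
RMSE = √(SSE/n) and RPD = 1/√(1 − Rp²). The RPD formula is sometimes
typeset without the square root, but only the rooted form is consistent
with published RPD values (Rp² = 0.890 → 2.9–3.0, not 9.1), and it equals
the population SD of the measured values divided by RMSEP — an identity
the tests check to 1e−10. The validation RMSE (RMSEV) comes from an inner
80/20 refit inside each calibration fold, since the outer protocol defines
only a two-way split. The full grid is 7 indices × 4 band sets × 6
families = 168 cells; per index the best model is the Rp² argmax, ties
broken by lower RMSEP, and per-cell failures are recorded without aborting
the grid.

## The synthetic testbed

The generator emulates the study conditions; its defaults are fixed, not
tuning knobs.

* **Design**: 2 cultivars × 6 treatments (25/4/−4 °C for 8/12 h) × 16
  plants, severity-ordered CK8 < CK12 < C8 < C12 < F8 < F12.
* **Biochemistry**: each marker is its treatment mean plus Gaussian noise,
  clipped to positivity at 1e−6 (clipping, not truncation — at high noise
  this biases means slightly upward; at the default noise levels the clip
  is never active). Treatment means follow the reported response
  directions — SPAD decreasing, SS/MDA increasing, enzymes rising under
  chilling and falling under freezing — and sit ≥ ~2.5 noise-sd inside the
  reported min–max envelope of each marker, so ≥99% of simulated values
  fall inside it. The enzyme curves rise modestly and collapse *below*
  control levels at −4 °C: severe freezing damages the enzymatic machinery
  itself. This choice is also structural: it keeps stress severity the
  dominant covariance axis of the panel, so the data-driven index is
  monotone in severity at zero noise — with a large symmetric chilling
  bump, the Kaiser rule retains a quadratic enzyme component whose
  variance-weighted contribution breaks monotonicity under any sign
  convention.
* **Spectra**: a smooth vegetation-like baseline (sigmoid red edge at
  ~715 nm rising from 0.2 to 0.65) minus one Gaussian absorption feature
  per marker (chlorophyll 665 nm for SPAD, 960 nm water/carbohydrate
  region for SS, 530 nm for MDA, red edge 715 nm for CAT, blue 445 nm for
  POD, far-NIR 985 nm for SOD), with depth proportional to the marker
  value. Every marker is therefore spectrally observable, which makes the
  index exactly linear in the noiseless spectra — the basis of the
  end-to-end recovery property (PLS Rp² > 0.99 with noise off). Per-sample
  multiplicative gain (0.95–1.05) and additive offset (±0.02) emulate the
  scatter class MSC removes, plus i.i.d. band noise (sd 0.002). Bands
  within one width of any feature centre are recorded as the
  informative-band ground truth.
* **Cubes**: leaf pixels carry a given spectrum plus pixel noise inside a
  centred block mask; background is a flat dark spectrum, constructed so
  threshold segmentation must succeed.

What the generator does *not* emulate: radiative transfer (no
PROSPECT-style leaf optics), instrument line shapes, spatially structured
leaf texture, cultivar-specific biology (the cultivar offset defaults to
0, as the source pools cultivars), or correlated band noise. Passing tests
therefore certify the algorithmic machinery — not field performance on
real leaves, whose published accuracy (e.g. Rp² ≈ 0.89 for the best
index model) cannot be reproduced without the unpublished data.

## Numerical and design choices

* Component signs: largest-|loading| entry positive; a fixture can impose
  an explicit sign pattern by supplying its own loading table.
* Variance contributions are computed from exact eigenvalues (100·λ/p);
  worked-example calculations feed the printed tables directly.
* Degenerate inputs: constant marker columns, empty ROIs, zero
  white–dark denominators, all-zero composite coefficients and band
  indices out of range raise informative errors naming the offender. A
  constant regression target short-circuits to an intercept-only model in
  families whose backends cannot represent it (epsilon-SVR).
* One plant yields one record; whether the source pooled the two sampled
  leaves per plant is unstated.
* Reproducibility: every stochastic operation takes a seed; the pipeline
  runner derives per-stage seeds from one global seed by stage-name
  hashing, and reruns produce byte-identical artifacts (MD5 digests in the
  run manifest).

## Problem sizes used in the shipped checks

The test-suite grid runs all 168 cells on the full 192 × 176 synthetic
dataset with selection in "once" mode and reduced deep-learning budgets
(CNN 4 epochs with 4/8/16 channels, LSTM 4 epochs, BP 20 epochs with 8
hidden units) — the cardinality and reporting contract is what is under
test there, not deep-model accuracy. Recovery and calibration properties
use 50 seeded replicates at reduced band counts (40–176 bands, 48–64
samples) with permutation baselines of 999 draws. The command-line entry
point of the analysis is R itself: the exported stage functions and
`run_pipeline()` compose the whole workflow.
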