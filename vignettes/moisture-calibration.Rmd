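---
title: "Calibrating pellet-feed moisture from NIR hyperspectral images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating pellet-feed moisture from NIR hyperspectral images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Moisture content drives the storability, nutritional stability and
palatability of compressed pellet feed. The reference determination is
gravimetric -- dry at 105 degrees C to constant mass and compute

$$H = 100\,\frac{M_1 - M_2}{M_1}\ \ [\%],$$

with $M_1$ the mass before and $M_2$ after drying
(`moisture_from_mass()`). It is slow and destructive. Near-infrared
hyperspectral imaging offers a fast, non-destructive surrogate: a
push-broom camera records a reflectance spectrum in every pixel
(here 256 channels spanning 935.5--2539 nm), the O--H combination and
overtone bands of water around 1450 and 1940 nm respond to moisture, and
a multivariate calibration maps spectra to percent moisture. Because each
pixel carries a spectrum, the same calibration also yields a
pixel-by-pixel moisture distribution map of the sample.

`pellspec` implements the full calibration chain and a synthetic scene
generator that stands in for instrument data, so that every stage is
testable end to end.

## From raw cube to calibration spectra

**Reflectance correction.** Raw detector counts $I_0$ are converted to
reflectance with the two-point calibration
$I = (I_0 - I_B)/(I_W - I_B)$, where $I_B$ is an all-black (lens cap)
frame and $I_W$ an all-white reference panel frame
(`correct_reflectance()`). Pixels where $I_W - I_B \le 0$ in any band are
excluded from the valid mask rather than clamped: silently clamping a
division by zero would propagate corrupted values into every later
statistic.

**Segmentation and averaging.** The pellet region is found by an
automatic two-class (Otsu) threshold on the band-averaged reflectance
image, followed by removal of connected components below a configurable
pixel count (`segment_sample()`). The spectra of all pellet pixels are
averaged per band into one calibration spectrum per sample
(`mean_spectrum()`).

**Edge trimming.** The first and last detector channels have low
signal-to-noise; `trim_bands()` keeps the closed interval
[960, 2489] nm, which on the uniform 256-channel grid retains exactly
244 bands. The closed-interval rule (endpoints kept) is what reproduces
that count.

## Outlier rejection by Monte Carlo cross-validation

`mccv_residuals()` repeats, 1000 times by default: draw a random 75 % of
samples, fit a PLS model, predict the held-out 25 %. Each sample
accumulates held-out residuals; their per-sample mean (MEAN) and standard
deviation (STD) position the sample in a MEAN--STD plane, where abnormal
samples separate from the main cloud. Screening runs on the trimmed raw
spectra, before any preprocessing.

Three design choices deserve explanation:

* **Component count.** Gross $y$-outliers drag the CV-optimal component
  count toward severe underfitting (the CV models chase the outliers in
  training), and an underfit screen inflates the residual spread of
  legitimate moisture-extreme samples. The internal choice therefore
  proceeds in two stages: a provisional count minimizes the *median*
  absolute held-out residual (outlier-robust), rows that are unambiguously
  deviant at that count (robust $z > 6$) are set aside, and the final
  count minimizes plain RMSECV on the remaining rows. The count is then
  held fixed across all Monte Carlo iterations.
* **Flag rule.** `flag_outliers()` flags a sample when its robust
  $z$-score exceeds 3 on the MEAN axis (two-sided) or on the STD axis
  (one-sided high -- an unusually *small* residual spread is not
  suspicious). The robust scale is the double MAD (median absolute
  deviation computed separately above and below the median): the STD axis
  is inherently right-skewed, and a symmetric MAD systematically
  over-flags its legitimate upper tail.
* **Cutoff.** The threshold of 3 is a declared convention for "obviously
  deviates"; it is configurable. The acceptance suite verifies that on
  default-condition synthetic data with 3 % of samples shifted by +8
  points the rule recovers every planted outlier while keeping the
  false-positive rate within 2 % across seeds.

## Spectral preprocessing

Seven operators are provided (`preprocess_fit()` / `preprocess_apply()`),
each as a fit-on-training / apply-to-anything transform so that training
statistics are reusable for test spectra and image pixels:

| method | definition | state |
|--------|------------|-------|
| SNV | per spectrum, $(x - \bar x)/s_x$, $n-1$ denominator | none |
| MSC | regress $x \approx a + b r$ on the reference $r$ (training mean), return $(x-a)/b$ | reference |
| FD | forward difference / $\Delta\lambda$, grid moves to interval midpoints | none |
| SD | central second difference / $\Delta\lambda^2$, interior channels | none |
| SG | least-squares polynomial (degree 3) over a 9-point window, evaluated as its 2nd derivative at the center | none |
| MC | subtract training column means | means |
| MMN | per band, $(x - \min)/(\max - \min)$ with training min/max | min/max |

Derivative outputs *shrink* (no edge padding) and the wavelength grid
shrinks with them -- fabricated edge values would otherwise enter
wavelength selection. The SG polynomial degree defaults to 3
(configurable); window 9 and derivative order 2 are the package's
defaults for the SG operator. MMN is per band; values of new data outside
the training range legitimately fall outside $[0,1]$ and are not clipped.
Constant spectra (sd or MSC slope below $10^{-12}$) raise an error, or --
in pixel-wise mapping -- mark the pixel missing.

## Wavelength selection

**CARS** (`cars_select()`). Competitive adaptive reweighted sampling runs
$N = 40$ Monte Carlo rounds. Round $i$ fits a PLS model on a random 80 %
of samples using the currently retained wavelengths, ranks wavelengths by
the normalized absolute regression coefficients
$w_i = |B_i| / \sum_j |B_j|$, and keeps the top
$\lceil r_i \, n \rceil$ of them, where the exponentially decreasing
function

$$r_i = \mu e^{-k i}, \qquad \mu = (n/2)^{1/(N-1)}, \qquad
  k = \frac{\ln(n/2)}{N-1}$$

starts at $r_1 = 1$ (all $n$ wavelengths) and ends at $r_N = 2/n$ (two
wavelengths): coarse elimination first, fine selection late. Each round's
retained set is scored by 10-fold RMSECV and the round with the smallest
RMSECV wins. Here $n$ is the total number of wavelengths -- the reading
under which the schedule's endpoints take their canonical values.

Two implementation decisions:

* The optional adaptive reweighted sampling draw (sampling
  $\lceil r_i n\rceil$ wavelengths with replacement by weight and keeping
  the unique ones) is implemented but **off by default**: the unique-draw
  attrition shrinks retention far below the EDF schedule, whereas the
  EDF-only variant retains exactly $\lceil r_i n \rceil$ wavelengths per
  round -- the regime in which a round-17-of-40 selection on a 244-band
  grid keeps 34 wavelengths, the canonical trace shape for this schedule.
* Each round is scored at its own best component count (up to a common
  cap of 10, chosen once on the full band): a fixed count cannot rank a
  240-wavelength subset and a 5-wavelength subset fairly.

Because the per-round models and the scoring folds reuse the same
calibration samples, the internal RMSECV trace is an optimistic estimate
wherever many noise wavelengths survive; the selection is therefore
validated downstream on a held-out test set.

**SPA** (`spa_select()`). The successive projections algorithm builds,
from each candidate start wavelength, a chain in which every next member
maximizes the norm of its component orthogonal to the previously chosen
one -- minimizing collinearity. Subsets (each chain prefix of size
$N_{min}..N_{max}$) are scored by 10-fold PLS RMSECV; the minimum wins,
with ties broken toward smaller subsets and then smaller start indices.
One chain per start is built once and its prefixes reused; `starts`
allows subsampling the start wavelengths when the exhaustive scan (all
columns) is unnecessarily expensive.

## Regression models and metrics

**PLSR** (`fit_plsr()`) implements SIMPLS with centered $X$ and $y$. The
model is stored both as a score-space factorization and as flattened
coefficients $(b_0, b)$; both prediction routes agree to numerical
precision, and at full rank the fit coincides with ordinary least squares
(both are tested against a normal-equations oracle). The component count
is chosen by 10-fold cross-validation (`select_nc()`, default cap 15,
rank-capped, ties toward fewer components).

**RFR** (`fit_rfr()`) delegates to the classical random-forest ensemble
(bootstrap rows, random feature subsets, mean aggregation) with
`min_leaf` mapped to the terminal-node size; `tune_rfr()` grid-searches
trees in 100..1000 by 100 and leaf sizes 1..10 by k-fold CV (default 5
folds, keeping the 100-point grid tractable), ties toward fewer trees and
larger leaves.

**Metrics** (`evaluate()`, `evaluation_report()`):
$R^2 = 1 - \sum(y-\hat y)^2 / \sum(y - \bar y)^2$ and RMSE on the
training set (RC2/RMSEC), in cross-validation (RCV2/RMSECV) and on the
test set (RP2/RMSEP); on the test set additionally
$\mathrm{RPD} = s_y / \mathrm{RMSEP}$ (with the $n-1$ standard deviation
of the test references) and the bias-corrected standard error
$\mathrm{SE} = \sqrt{\sum(e - \bar e)^2/(n-1)}$. A model with
$\mathrm{RPD} > 3$ is considered usable for quantitative work, and an SE
below twice the laboratory's SEL is considered excellent.
`sel_from_replicates()` uses the duplicate-difference convention
$\mathrm{SEL} = \sqrt{\sum d_i^2 / (2m)}$.

## The synthetic study population

`generate_spectra()` draws, for sample $i$ with moisture $H_i$:

$$x_i(\lambda) = g_i\left[b(\lambda) + d_i(\lambda) + H_i q(\lambda) +
  \textstyle\sum_k c_{ik} n_k(\lambda)\right] + o_i +
  \varepsilon_i(\lambda)$$

* $b$: fixed quadratic baseline (reflectance about 0.64--0.74);
* $q$: water absorption profile -- Gaussian dips at 1450 nm (width 45 nm)
  and 1940 nm (width 55 nm) with depths 0.030 and 0.040 reflectance units
  per percent moisture. The depths were chosen so that the water bands
  dominate the spectrum's dynamic range without saturating it (dips up to
  roughly 0.45 at 14 % moisture, minimum reflectance about 0.12), the
  situation in real feed spectra, where water is by far the strongest
  NIR absorber. Derivative preprocessing only carries usable information
  when the absorption signal stands well above the channel-noise floor,
  so shallow-dip settings would not represent the intended regime;
* $n_k$: dry-matter constituent dips (protein/fat/cellulose-like bands at
  1100, 1720, 2300 nm) with per-sample relative concentrations
  $c_{ik} \sim \mathcal N(1, 0.1)$ -- a manufactured feed's composition
  varies by roughly ten percent, and this stable absorption signature is
  what allows scatter-affected models to anchor the per-sample gain;
* $g_i \sim \mathcal N(1, 0.05)$ and $o_i \sim \mathcal N(0, 0.02)$:
  multiplicative scatter and additive offset -- exactly the distortions
  MSC and SNV are designed to remove, making those operators testable;
* $d_i$: per-sample quadratic baseline perturbation (sds 0.010 / 0.005 /
  0.003 per degree);
* $\varepsilon$: iid channel noise, sd 0.002 reflectance units.

With all random terms silenced the moisture-to-spectrum map is exactly
affine, and the recorded ground truth ($q$, the per-sample gains, the
true per-pixel moisture field of scenes) serves as the oracle in the
recovery tests. Reference values emulate a moisture-controlled
population: 90 % of samples uniform in 8--14 %, the remainder ("other")
in 4--8 %, everything below 14 % (`generate_reference_values()`; the
distribution is a configurable stand-in, not a claim about any real
population). Defaults: 144 samples, seed 20230901.

`generate_scene()` lays elliptical pellets on a dark, spectrally flat
background, adds a smooth within-pellet moisture field (sd 0.3
percentage points) so maps show structure, and emits matching all-black
and all-white calibration cubes such that reflectance correction is
exact by construction.

What the generator does **not** emulate: inter-channel correlated
(smooth) spectral noise, instrument line-shape and stray light,
temperature and path-length effects, pellet 3-D geometry and shading,
and any particular camera's radiometry. Passing tests therefore
demonstrate that the statistical machinery of the chain is correct and
recovers known structure under realistic noise magnitudes -- not that the
package has been validated against a physical instrument.

## Pipeline order and what the held-out metrics mean

`run_pipeline()` executes: simulate -> trim -> MCCV rejection ->
preprocess -> wavelength selection -> 75/25 split -> model fit ->
evaluation -> pixel map. Wavelength selection runs on the full
post-rejection population, the standard order in chemometric calibration
transfer; the held-out metrics therefore validate *the regression model
given the selected wavelengths*, not the selection step itself. (A
selection-inclusive validation would need an outer resampling loop,
out of scope here.) For stateful preprocessing operators the pipeline
fits transform statistics on the post-rejection calibration population;
the default SD operator is sample-wise and stateless, and the
module-level API supports strict train-only fitting where desired.

The train/test split is random 75/25 by default (mirroring the MCCV
convention); Kennard--Stone (max--min spectral distance) is available via
the split configuration.

## Numerical conventions

* Constant-row tolerance $10^{-12}$ (SNV sd, MSC slope); PLS rank
  exhaustion at $10^{-10}$ of the first score norm; EDF closed form exact
  to $10^{-12}$.
* Ties: RMSECV argmins break toward the earlier CARS run, the smaller
  SPA subset then smaller start, the smaller PLS component count, fewer
  RFR trees then larger leaves.
* Degenerate inputs are errors with messages (empty masks, uniform
  segmentation images, inverted intervals, white $\le$ dark everywhere),
  except in pixel-wise mapping, where per-pixel preprocessing failures
  mark pixels missing and are counted in the map report.
* Every stochastic routine takes an explicit seed and restores the
  caller's RNG state; fixing the seed fixes every output bit for bit.

## Problem sizes

The test suite and the acceptance script run the chain at the study's
own scale -- 144 samples by 244 trimmed bands, 1000 MCCV iterations, 40
CARS rounds, 120 x 160 scenes -- which keeps the full suite under a
minute of compute for the unit tests and a few minutes end to end.
Module-level unit tests use smaller populations (20--60 samples) where
the property under test does not depend on scale.

## Known limitations

* The instrument-facing I/O implements the plain ENVI dialect
  (little-endian, types 2/12/4/5, BSQ/BIL/BIP) -- not vendor extensions.
* The MCCV flag rule errs on the cautious side: a few percent of clean
  samples at the moisture extremes can be flagged. The cutoff is a
  convention and should be reviewed against a MEAN--STD plot for any new
  data set (the report object carries the coordinates for exactly that
  purpose).
* The internal CARS RMSECV trace is optimistic in the presence of many
  uninformative channels (selection and scoring share samples); rely on
  the held-out metrics for model quality.
* SPA's exhaustive start scan is $O(p)$ chains with $O(N_{max})$ scored
  prefixes each; on full-resolution spectra prefer the `starts` argument
  or CARS when runtime matters.
```
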