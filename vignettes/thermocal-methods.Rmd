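---
title: "Calibrating uncooled UAV thermal imagery and preparing it for photogrammetry"
author: "thermocal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating uncooled UAV thermal imagery and preparing it for photogrammetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermocal)
```

## The measurement problem

Light UAV payloads force the use of uncooled, TEC-less microbolometer
cameras. Without a thermo-electric cooler the detector's own temperature
drifts with ambient conditions and self-heating, and the raw digital
response (DL, counts) to a scene of fixed temperature drifts with it, in a
nonlinear way. A calibration that maps counts alone to temperature is
therefore not enough: the sensor temperature (TC, recorded per acquisition)
must enter the model. A second, independent problem is that thermal scenes
span only a few degrees, so raw frames have very low contrast and
structure-from-motion software finds too few tie-points to orient the image
block reliably.

`thermocal` addresses both: it fits (DL, TC) → temperature calibration
models against blackbody reference data and evaluates them, and it
implements Wallis local-contrast filtering with a transparent
Harris-plus-NCC tie-point surrogate to quantify how much filtering improves
matching.

## Calibration models

With TBB the blackbody reference temperature, the polynomial family is

* `LINEAR_DL`: TBB = p00 + p10·DL (the DL-only baseline);
* `P1`: TBB = p00 + p10·DL + p01·TC;
* `P2`: adds DL², DL·TC, TC²;
* `P3`: adds DL³, DL²·TC, DL·TC²;
* `P4`: adds TC³.

Coefficients `pij` (DL power i, TC power j) are estimated by ordinary least
squares. Because DL is of order 10³–10⁴, cubic design columns reach 10¹¹
and a naive normal-equations solve loses several digits; `fitPolynomial()`
therefore solves by QR on a column-equilibrated design (each column scaled
to unit norm, coefficients rescaled afterwards). On data generated exactly
from a quadratic model this recovers the generating coefficients to better
than 1e-6. Rank-deficient designs (for instance a constant TC with a TC
term in the model) raise a singular-fit error naming the collinear terms
rather than silently pseudo-inverting.

The neural-network variant is a single hidden layer of tanh units with a
linear output: S_j = w0j + Σ w_ij x_i, y_j = tanh(S_j). Inputs and target
are standardized by the calibration subset's mean and SD. Design choices,
made once:

* hidden size 10 — the smallest standard topology that comfortably
  represents a smooth two-input response;
* seeded uniform(−0.5, 0.5) initialization, full-batch gradient descent
  with momentum 0.9 on the mean squared error — dependency-free and exactly
  reproducible given the seed;
* learning rate 0.05 on the standardized problem. With 0.01 the optimizer
  is still far from converged after 5000 full-batch epochs on a ~170-record
  calibration subset, while 0.05 reaches a validation RMSE well below the
  quadratic model's approximation floor in the same budget and remains
  stable; larger rates gain little and risk oscillation;
* epoch cap 5000 with early stopping after 200 epochs without
  validation improvement, returning the best-on-validation snapshot. This
  is a deliberate guard against overfitting the small calibration subset.

Training diverging to a non-finite loss raises an error advising a smaller
learning rate instead of returning garbage weights.

## Calibration/validation split

65% of records go to calibration, 35% to validation. Rather than a simple
random draw, records are stratified by their rounded blackbody setpoint and
sampled within each bin with a largest-remainder allocation, so the overall
65% is hit exactly (within one record) and *both* subsets span the whole
temperature range — a plain random split can leave an extreme setpoint
entirely in one subset, which silently turns interpolation into
extrapolation. Bins holding one record go to calibration with a warning.
The draw is deterministic given the seed.

## Scoring and residual diagnostics

`fitReport()` bundles n, the series means, R² (squared Pearson correlation
on the observed/simulated pairing), RMSE, relative error
(100·RMSE/mean(observed), %), and the similarity index

SI = 1 − Σ(S−O)² / Σ(|S−MO| + |O−MO|)²,

Willmott's index of agreement. The variant that sums the *signed*
deviations in the denominator is available behind `literal = TRUE`; it can
degenerate when deviations cancel, which is why the absolute-value form is
the default.

`residualDiagnostics()` regresses observed on simulated and reports the
slope/intercept with standard errors, a Shapiro–Wilk normality p-value on
the residuals, a Breusch–Pagan (studentized) p-value for variance
constancy, and Cook's distances with the common 4/n flagging threshold.
The test names are recorded in the object so reports are self-describing.
Monte-Carlo checks in the test suite confirm the normality test holds its
nominal size on normal residuals and that variance growing with the
simulated value is detected with high power at n = 200.

## Wallis filtering

Raw 14-bit counts occupy a narrow band of the 16-bit container, so frames
are first stretched to an 8-bit working range by mapping the 2nd/98th
percentiles to 0/255 (clipped; a constant image maps to mid-gray). The
filter itself is the classical two-constant form

G′ = (G − m) · c·s_t / (c·s + (1−c)·s_t + ε) + b·m_t + (1−b)·m,

with m, s the local mean and population SD over an odd window (reflection
padding at the edges; summed-area tables make the cost independent of the
window size), targets m_t = 127 and s_t = 50, contrast c = 0.8, brightness
b = 0.9, and ε = 1e-6 guarding flat windows. Output is clipped to [0, 255]
and rounded. All constants are exposed as parameters and CLI flags. Note
that c bounds the local amplification by c/(1−c) = 4, so global SD gains
beyond about 4× come from the stretch-plus-filter pipeline, not from the
transform alone.

## The tie-point surrogate

The photogrammetric matcher the survey results came from is proprietary;
counting its tie-points cannot be reproduced offline. The package instead
measures the *effect of filtering* with a transparent pipeline: Harris
corner response (central-difference gradients, Gaussian structure tensor
with σ = 1.5, k = 0.05), 3×3 non-maximum suppression, a relative response
threshold, then normalized cross-correlation matching of 11×11 patches
with mutual-best pairing and an 0.8 acceptance threshold. Counts produced
this way are comparable to a real SfM run in *trend only*, never in
magnitude.

The default relative threshold is 1e-4 of the maximum response. The Harris
response scales as contrast to the fourth power, so this admits corners
within roughly 10% of the maximum contrast — with the conventional 0.01
only features within ~32% of the strongest corner survive, which on
thermal imagery means "only the hottest object", defeating the purpose of
the measurement.

## GCP accuracy and field validation

`gcpSummary()` reduces a table of signed per-GCP errors (estimated minus
surveyed coordinate) to per-axis RMS values and the total 3-D error, the
root of the mean squared per-GCP Euclidean error; the identity
total² = rmsX² + rmsY² + rmsZ² holds exactly and is tested. All error
tables are interpreted in meters. `validationCompare()` pairs field
reference temperatures with orthoimage-product temperatures and reports
the RMSE, maximum absolute difference, sample (n−1) SD of the differences,
mean bias and a full fit report. The packaged example tables from a
vineyard UAV survey reproduce the published summary rows of their source
(axis RMS 2.66/2.45/6.20 m and total 7.18 m unfiltered against 1.23 m
filtered; validation RMSE 2.6 °C with difference SD 2.7 °C).

## What the synthetic generators emulate

**Blackbody campaign.** One record per (setpoint, sensor temperature)
combination with setpoints 5–65 °C in 5 °C steps and twenty sensor
temperatures between 5 and 31 °C, denser above 20 °C (cooling-room
sessions yield fewer acquisitions), 260 records in total. The forward
model is

DL = offset + k1·(TBB + 273.15)⁴·10⁻⁸ + k2·(TC − t0) + k3·(TC − t0)²+ noise,

a T⁴ radiance proxy rather than a band-integrated Planck model — adequate
over 5–65 °C in the 7.5–13.5 μm band and simple enough to reason about.
Defaults: k1 = 30 counts per radiance unit puts counts near 7000–9000 with
a sensitivity of ~32 counts/°C; drift k2 = −12 counts/°C and k3 = −0.3
counts/°C² amount to roughly 10 °C-equivalent of uncompensated drift
across the 26 °C sensor range, a realistic TEC-less magnitude that still
leaves the quadratic model family within a quarter degree on noiseless
data; noise SD 16 counts ≈ 0.5 °C. Noiseless count overflow of the 16-bit
container is a configuration error.

**Model-ordering conditions.** Ordering comparisons between the network
and the polynomial family are run on *noiseless* campaigns: with the
default 0.5 °C-equivalent noise both P2 and the network sit at the noise
floor and their ordering is dominated by sampling variation rather than
capacity, which is not what an ordering check probes. Noiseless campaigns
isolate each model's approximation error. The noisy default instead feeds
the estimator-sanity check (best validation RMSE between 0.35 and 0.75 °C
at the 0.5 °C noise level).

**Scene pairs.** A smooth random thermal field (amplitude 60 counts), many
weak fine-texture blobs (40 blobs, 10 counts — the matchable detail), a
couple of strong point-like "hotspot" objects (±2500 counts — reflective
targets, bare soil) and camera-fixed radial vignetting; the second frame
is the scene translated by a known integer offset with fresh noise.
Because the hotspots own the dynamic range, a min–max display stretch
leaves the background texture at a handful of gray levels — the
low-contrast regime (display SD under 10 levels) is quantified on that
min–max mapping, since a 2/98 percentile stretch pins 4% of pixels to the
range ends and cannot have a global SD much under 25 regardless of the
scene. These scenes do not emulate real thermal imagery's non-uniformity
patterns, shutter events, defective pixels or perspective distortion, so
passing tests demonstrate the filtering mechanism, not performance on any
particular camera.

**GCP tables.** Zero-mean Gaussian signed errors per axis; large simulated
tables recover their generating SDs, anchoring the summary arithmetic.

All generators are bit-reproducible given (config, seed); library code
saves and restores the caller's RNG state.

## Numerical and interface conventions

* ROI selections are 0-based, half-open, matching the
  `rmin,rmax,cmin,cmax` CLI convention; keypoint coordinates are 1-based
  matrix indices, the R idiom.
* Reflection padding is symmetric (edge pixel included), applied
  identically in local statistics, convolution and gradients.
* Non-maximum suppression keeps points not smaller than any 3×3 neighbor;
  ordering ties are broken by row then column so detection is fully
  deterministic.
* Temperature maps are written as 32-bit IEEE float, single-strip,
  little-endian grayscale TIFF in °C. The package carries its own small
  writer/reader for this layout because the available TIFF bindings only
  store values in [0, 1]; files are readable by standard TIFF libraries.
* Raw frames are 16-bit grayscale TIFF with a JSON sidecar carrying
  `sensor_temperature_c`; no vendor raw formats, no GeoTIFF georeferencing.
* Model files are JSON with either the coefficient list or the full weight
  and scaling set, and round-trip to identical predictions.

## Problem sizes in the test suite

The suite runs campaign fits at the default 260-record size, the 20-seed
ordering study on noiseless campaigns, tie-point comparisons on ten
96×96-pixel scene pairs spanning a range of texture strengths, and oracle
comparisons (double-loop local statistics, Wallis transform, structure
tensor, ROI means, agreement statistics) on instances up to 32×32. These
sizes keep every property deterministic and quick while remaining large
enough that the stratified split, early stopping and rank statistics are
exercised meaningfully.

## Known limitations

* Tie-point counts are a surrogate: trends and percentages transfer,
  absolute counts do not.
* The calibration models ignore shutter/non-uniformity/defective-pixel
  effects (assumed handled by camera firmware) and perform no atmospheric
  or emissivity correction.
* The similarity index, relative error and R² are computed on whatever
  pairing they are given; selecting a validation subset is the caller's
  responsibility (the fitting functions and CLI do this for you).
* The synthetic sensor is not a model of any real device's response
  function; its gains were chosen once to produce plausible count ranges.
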