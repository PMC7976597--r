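---
title: "Digital compartment analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital compartment analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gelbead)
```

## The assay and its statistical model

A digital compartment assay splits a reaction into thousands of nanolitre
partitions — hydrogel beads (Gelbeads) or droplets — so that target
entities (cells or template copies) land in partitions according to a
Poisson law with mean occupancy $\lambda$. Reading each partition as
positive (bright) or negative (dark) turns concentration measurement into
counting: the negative fraction estimates the Poisson zero class
$p_0 = e^{-\lambda}$, and

$$\hat\lambda = -\ln\frac{n_{neg}}{n_{tot}}, \qquad
  \hat c = \frac{1000\,\hat\lambda}{v}\ \text{copies/}\mu\text{L}$$

for partition volume $v$ in nL. Everything in this package either prepares
that readout from images (segmentation, intensity measurement, threshold
fitting) or consumes it (concentration estimation, dynamic range,
dilution-series regression).

The key modelling assumptions are:

* occupancy is Poisson and independent across compartments — true when
  entities are well mixed and dilute relative to the total volume;
* a compartment is positive if and only if it contains at least one
  entity — the default intensity model; real assays can break this link
  (dye crosstalk at very long incubations, inhibited amplification);
* the partition volume is treated as a single population value. Diameter
  CVs of 4–8 % translate to volume CVs of roughly three times that, but
  because the estimator depends on volume only through the linear scale
  factor $1000/v$, using the population mean diameter biases concentration
  by under a percent at these CVs; the dispersion is deliberately not
  propagated into the CI.

## The synthetic scene generator

`SceneParams()` / `sampleCompartments()` / `renderTwoChannel()` generate
the ground-truthed inputs every stage is tested against.

* **Diameters** are lognormal, parameterised directly by arithmetic mean
  and CV ($\sigma_{\log}^2 = \ln(1+cv^2)$). Only mean and CV are
  meaningful monodispersity summaries for emulsions, and the lognormal
  guarantees positive diameters; a zero CV degenerates to identical
  diameters. Defaults: mean 175 µm (the 2.8 nL standard design), CV 5 % —
  the midpoint of the 4–8 % range typical of centrifugal droplet
  generation.
* **Placement** is rejection sampling with a 10⁴-attempt budget per
  compartment, largest first, keeping ≥ 2 px clearance between rims and to
  image borders. Failure reports the achieved packing fraction. Touching
  compartments are therefore never produced by placement; they arise only
  through the heating simulator, which is also why segmentation's
  watershed-splitting path is exercised separately.
* **Intensities** form a two-level step model: the reference channel
  (calcein/FITC-like) paints every compartment at one level, the signal
  channel (TXR/FAM-like) at a positive or negative level, both over a
  uniform background with i.i.d. Gaussian noise, clipped to the unsigned
  16-bit camera range. Defaults (10000 / 8000 / 1000 over background 200,
  noise sd 50 ADU) give ratio separations far beyond the ≥ 4 regime in
  which mixture classification is near-perfect — deliberately: tests of
  the chain should fail on logic, not on borderline photometry. The radial
  intensity structure real amplified beads can show is not modelled.
* **Spot mode** renders each entity as a Gaussian spot (σ = 2.5 µm
  default, a bacterium-scale point signal) for cell-counting tests.
* **Heating** (`simulateHeating()`) merges each unordered
  nearest-neighbour pair with probability `mergeProb` into a compartment
  of diameter $(d_1^3+d_2^3)^{1/3}$ at the volume-weighted centroid
  (volume and entity counts conserved exactly), then shrinks every
  survivor's diameter by $(1-f_{evap})^{1/3}$. This captures the two
  degradation routes of heated emulsions — merging broadens the size
  distribution upward, evaporation shifts it downward — but not their
  kinetics; `mergeProb` and `evapFraction` are per-protocol net effects,
  not rates.
* **Seeding**: every operation derives its own sub-stream from the scene
  seed plus a fixed per-operation offset, so adding a stage never perturbs
  draws made by earlier ones, and all outputs are bit-identical for a
  fixed seed.

What passing tests on these scenes does *not* show: robustness to uneven
illumination, out-of-focus compartments, radial intra-bead patterns, or
overlapping compartments in the raw emulsion — none of which the generator
emulates.

## Segmentation choices

Detection is Otsu thresholding of the reference channel, hole filling,
connected-component labelling, then a distance-map watershed applied only
to components whose circularity falls below the acceptance minimum —
splitting fused beads without risking over-segmentation of clean disks.
Geometry is reported in a 0-based pixel-centre convention; diameters come
from the equivalent-area circle and are converted to µm by the user-supplied
pixel size (objective magnifications vary, so µm/px is always an explicit
input, never inferred).

Numerical details worth knowing:

* **Circularity** $4\pi A/P^2$ uses a chain-code perimeter with
  Vossepoel–Smeulders step weights (0.948 axial, 1.340 diagonal); the raw
  boundary-pixel count underestimates digitised circular perimeters enough
  to push the ratio far above 1. Residual digitisation still lets perfect
  disks exceed 1 slightly, so the value is clamped at 1.0. The default
  acceptance minimum is 0.85.
* **Size filters** `dMin`/`dMax` bound accepted diameters; the upper bound
  also removes chamber loading ports, which image as much larger bright
  circles than any compartment.
* **Border-touching** compartments are flagged and retained in tables but
  excluded from size statistics (their areas are truncated).
* **Intensity means** are taken over the disk eroded by 2 px (default) to
  avoid rim mixing; the signal/reference ratio is undefined — flagged
  `NA`, not zero — when the reference mean does not clear the background
  estimate.
* **Size statistics** use the sample (n−1) standard deviation for the CV,
  linear-interpolation percentiles (R type 7), and whiskers at the
  10th/90th percentiles with outliers strictly outside them — the
  whisker convention used for emulsion monodispersity plots, not Tukey's
  1.5·IQR.
* **Spot counting** smooths at half the expected spot σ, takes local
  maxima above median + 0.3 × (max − median) with an 8·MAD robust noise
  floor, and merges maxima closer than `minSeparation` by non-maximum
  suppression — so two genuinely adjacent cells count as one, a documented
  under-count rather than a noise-driven over-count.

## Threshold fitting and classification

`fitBimodalThreshold()` fits a two-component Gaussian mixture by EM
(k-means split initialisation, relative log-likelihood tolerance $10^{-8}$,
500-iteration cap) and places the threshold at the density-intersection
point between the means, which minimises expected misclassification under
the fitted model; when no intersection lies between the means (extreme
weight imbalance) it falls back to their midpoint. With equal spreads and
weights this reduces to the midpoint exactly. The separation index
$|\mu_+-\mu_-|/\sqrt{\sigma_-\sigma_+}$ is always reported; below 2 the
fit is marked non-converged and a manual threshold is advised. Samples
under 20 values are refused outright — EM on so few points silently
overfits.

Classification is strict (`value > threshold`), with ties negative: the
conservative direction for concentration estimation, since a spurious
positive inflates $\hat\lambda$. The positive-fraction CI is a Wilson score
interval, preferred over Wald for its small-n and near-boundary behaviour.
Ratios (signal/reference) are the classification variable for two-channel
phenotyping; raw signal means serve single-channel amplification runs. All
values of one sample are pooled and fitted together, and one threshold is
applied across a timecourse, keeping timepoints comparable.

## Quantification details

* The concentration CI uses the delta-method variance of $\hat\lambda$ —
  closed-form, testable, and accurate at the partition counts of interest
  (measured 95 % CI coverage at $n = 7000$ stays within the low-to-mid
  nineties across $\lambda \in \{0.1, 1, 3\}$ in the acceptance script). A
  seeded percentile bootstrap is available behind the same interface.
* An all-negative run returns concentration 0 with CI upper bound
  $1000\cdot 3/(n v)$ (three expected copies); an all-positive run raises
  a "saturated" error carrying the $\ln n$ lower bound rather than
  returning a number that would be read as an estimate.
* **Dynamic range** is computed from explicit, pluggable criteria: LOD is
  the smallest concentration giving ≥ 3 positive partitions with 95 %
  probability (binomial); the lower quantification bound is where the
  relative CI width reaches 25 %; the upper bound is where expected
  negatives fall to 3. At small partition counts the 25 % width criterion
  can be unattainable at any concentration; the lower bound then falls
  back to the best-precision point (the width minimum), preserving
  LOD ≤ lower < upper. These rules are one defensible choice among
  several in use; the criteria travel with the result object so reported
  ranges are always interpretable.
* **Goodness of fit** pools occupancy bins from the top (the last bin
  absorbing the upper tail) until every expected count is ≥ 1, then uses
  the chi-square statistic with one degree of freedom deducted when
  $\lambda$ is fitted by its MLE, the sample mean.

## Efficiency regression

Dilution-series comparison regresses estimated on reference concentration
by OLS with a free intercept (an intercept detects additive bias;
through-origin and log-axis variants are flags). The slope's standard
error defaults to the HC3 heteroskedasticity-robust sandwich estimator
rather than the classical homoskedastic formula: digital concentration
estimates have variance that grows with concentration, and on simulated
dilution series of this design the classical formula understates the slope
uncertainty enough to break its own nominal coverage (measured ≈ 88 % for
a ±3 SE band across repeated simulated series, against ≈ 95 % for HC3).
The classical value remains available via `seType = "ols"`.

## Problem sizes

The shipped tests and the acceptance script run at sizes chosen to make
the statistical assertions sharp while keeping a full run interactive:
20 noiseless 50-compartment scenes for segmentation fidelity, a
500-compartment $\lambda = 1$ scene for the phenotyping endpoint,
$5 \times 3$ dilution points at 7000 partitions for the efficiency
regression, 200 replicates per $\lambda$ for CI calibration, and pooled
draws totalling $10^5$ occupancies for the Poisson-histogram property.

## Known limitations

* No optics model: no PSF, defocus blur, or vignetting; counts of cells in
  thick spherical compartments under high magnification will under-report
  out-of-focus cells in ways the generator cannot emulate.
* The two-level intensity model omits radial intra-bead amplification
  patterns and inter-compartment dye leakage.
* Per-partition volume dispersion enters the estimator only through the
  population mean (see above), not the CI.
* Heating adjacency is nearest-neighbour only; chain merges of three or
  more compartments in one protocol are not modelled.
* Time-lapse tracking and z-stacks are out of scope.
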