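---
title: "Forest monitoring with forestpulse: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forest monitoring with forestpulse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`forestpulse` chains the classical ingredients of satellite forest
monitoring — radiometric calibration, Gaussian maximum-likelihood
land-cover classification, confusion-matrix accuracy assessment,
change-detection cross-tabulation, and the NDVI/LST/VCI/ECI index
family — into one seeded, testable pipeline. This vignette is the
package's own account of the science: what each stage assumes, which
parameters matter, what the synthetic data generator does and does not
emulate, and where design choices were genuinely open.

## The classification model

Each land-cover class $c$ is modelled as a multivariate Gaussian over
the reflective bands with mean $\mu_c$, covariance $\Sigma_c$ and prior
$a_c$. A pixel $X$ receives the weighted distance

$$D_c(X) = \ln a_c - \tfrac12 \ln |\Sigma_c|
          - \tfrac12 (X-\mu_c)^\top \Sigma_c^{-1} (X-\mu_c),$$

which is the log of the prior-weighted Gaussian density up to the
class-independent constant $-\tfrac{k}{2}\ln 2\pi$; the label is
$\arg\max_c D_c$, i.e. the Bayes rule under the model. Assumptions worth
keeping in mind: class-conditional normality (adequate for broad LULC
composites, wrong for multimodal classes), and priors that default to
equal because no class-abundance prior is usually defensible a priori —
`fitClassModels(training, priors = ...)` overrides them.

Numerical conventions:

* covariances use the $n-1$ denominator and require at least
  `bands + 1` samples per class;
* a near-singular covariance gets a ridge of $10^{-6}$ times its mean
  diagonal with a warning; fitting fails only if it remains singular;
* argmax ties resolve to the lowest class index, so classification is
  deterministic;
* the thermal band is excluded from the feature vector — the classifier
  operates on the reflective composite;
* there is no reject class: every valid pixel is labelled, so area
  accounting is exhaustive.

The 3×3 majority filter replaces each valid pixel by the modal label in
its window, keeps the original label on ties, and never invents a label
absent from the window. Edge windows truncate.

## Accuracy assessment

Reference points are drawn by stratified random sampling: proportional
to class share with a floor of 5 points per present class,
largest-remainder rounding so the allocations sum to the requested
total (600 by default, a common figure for district-scale assessments),
without replacement within class. Points landing on nodata are
excluded rather than resampled, which keeps the sampler a pure function
of (map, seed).

The confusion matrix is oriented rows = map, columns = reference.
Producer's accuracy divides the diagonal by column totals (omission
errors); user's accuracy by row totals (commission errors); kappa uses
the standard marginal-product chance correction. The report flags
actionability at kappa ≥ 0.75, a conventional threshold for
decision-grade maps.

## Change detection

`crosstab` counts jointly valid pixels only (nodata in either date
removes the pixel from both), which makes the conservation laws exact:
row sums equal date-1 class areas, column sums date-2 areas, total
gains equal total losses, and `crosstab(a, b)` is the transpose of
`crosstab(b, a)`. Areas are pixel counts times pixel area
(0.0009 km² at 30 m). Report tables round areas to 2 decimals and
percents to 1 decimal — internal arithmetic is unrounded — and the
percent denominator is configurable between total geographic area and
valid mapped area, since published tables often fix the former.

## The index chain

* **NDVI** $(NIR-RED)/(NIR+RED)$, clamped to $[-1,1]$; undefined where
  $NIR+RED=0$. Density classes: non-vegetation $<0$, low $[0,0.2)$,
  moderate $[0.2,0.5]$, high $>0.5$; the 0.5 boundary is read as
  inclusive-upper for moderate and both boundaries are configurable in
  spirit — the bins are deliberately half-open to make them exhaustive
  and disjoint.
* **Proportion of vegetation** $PV = ((NDVI - NDVI_{min}) /
  (NDVI_{max} - NDVI_{min}))^2$ with *per-scene* extrema.
* **Emissivity** $\varepsilon = m \cdot PV + n$ with $m = 0.004$,
  $n = 0.986$ — a linear mixing model whose coefficients absorb the
  soil and vegetation endmember emissivities; bare soil maps to 0.986,
  full canopy to 0.990.
* **Brightness temperature** $TB = K_2 / \ln(K_1/L + 1)$ (inverse
  Planck) from thermal radiance; nonpositive radiance is nodata.
* **LST** by the standard single-channel emissivity correction
  $LST_K = TB / (1 + (\lambda\, TB/\rho)\ln\varepsilon)$, returned in
  °C. $\lambda$ is the effective thermal wavelength (11.5 µm for the
  TM-like band 6, 10.8 µm for an OLI/TIRS band 10);
  $\rho = h c / k_B$, used at its conventional rounded value
  $1.438\times10^{-2}$ m·K (`thermalRho()` recomputes it from physical
  constants; the CODATA value is $1.4388\times10^{-2}$). At
  $\varepsilon = 1$ the correction vanishes and $LST_K = TB$ exactly.
* **VCI** $= 100 (NDVI - NDVI_{min})/(NDVI_{max} - NDVI_{min})$ with
  *per-pixel extrema across the multi-date stack* — the deliberate
  contrast with PV's per-scene extrema matters: PV normalizes within an
  image, VCI against a pixel's own history. Drought classes: non
  $[50,100]$, mild $[30,50)$, moderate $[20,30)$, severe $[10,20)$,
  extreme $[0,10)$.
* **Histogram equalization** is global rank-based with average ranks
  for ties, mapping to integers in 1–255; a constant grid maps to the
  midpoint 128. Rank equalization was chosen over bin-counting
  dialects because it is exactly monotone, deterministic and
  tie-stable.
* **ECI** $=$ stretched LST / stretched NDVI. The stretch floor of 1
  keeps the ratio defined everywhere. Water and other non-vegetated
  pixels are *not* masked by default — masking them is recommended for
  interpretation and available via `eci(..., maskNonveg = TRUE)`.
  Criticality classes default to terciles of the valid pixels (no
  universal fixed breaks exist for a ratio of equalized layers); fixed
  breaks can be supplied.

## The synthetic study conditions

The generator exists so that every downstream stage can be tested
against known truth. Its defaults are fixed study conditions, chosen
once:

* 128×128 pixels at 30 m, four dates, a 2-pixel nodata border;
* class fractions FC 0.70, AG 0.15, BS/WB/OT 0.05 each — a
  forest-dominated dry-zone landscape;
* landscape model: white noise smoothed by a Gaussian kernel
  (Toeplitz smoothing matrices, rows normalized, so edges are handled
  exactly) and rank-cut at the cumulative fractions. This yields
  contiguous patches whose diameter scales with `patchScale`
  (default 8 px) and realized fractions exact to pixel rounding;
* class spectra: six TM-like reflective bands with per-band standard
  deviation 0.02, means chosen so the NDVI ordering is
  forest > agriculture > other > built-up > water and the closest
  class pair sits ≥ 5 within-class standard deviations apart — a
  regime in which a correct maximum-likelihood implementation should
  essentially saturate accuracy, which is the point of the test;
* thermal coupling TB = 310 K − 10 K · NDVI + N(0, 0.2 K), encoded to
  DN through the forward Planck relation with the TM band-6 constants
  (K1 = 607.76, K2 = 1260.56, gain 0.055158, offset 1.2378) so the
  decoding chain is genuinely exercised;
* scripted change: per date step, 2% of forest converts to agriculture
  and 1% to built-up, placed preferentially at patch edges (ranked by
  the smoothed non-forest indicator), emulating conversion along
  boundaries and roads.

What the generator does **not** emulate: atmospheric radiative
transfer, topography, clouds and shadows, sensor PSF, mixed pixels,
phenology, or spatially correlated within-class noise. Passing the
end-to-end recovery tests therefore demonstrates that the
implementation is correct under its own model, not that the pipeline
would reach the same accuracy on real imagery.

## Preprocessing conventions

Calibration is the per-band affine map L = gain·DN + offset.
Dark-object subtraction uses the 1st percentile of valid pixels as the
dark value (robust to single-pixel outliers; the absolute minimum is
not), clips at zero and never touches the thermal band. Whether NDVI is
computed from radiance, TOA reflectance or surface reflectance is left
to the user's calibration choices; the index chain operates on whatever
calibrated quantity the scene carries, and the synthetic round trip
uses reflectance. Clipping masks pixels whose centers fall outside the
AOI polygon (even-odd rule) and never alters surviving values;
nearest-neighbor resampling introduces no new values and is therefore
safe for categorical maps. No operation ever turns a nodata pixel
valid. Inputs must share a CRS; there is no reprojection engine.

Because no binary geospatial format library is required, rasters are
exchanged as ESRI ASCII grids (one per band) with a JSON sidecar
holding CRS, date, processing stage and sensor calibration. Floats are
written with 9 significant digits (full float32 fidelity).

## Reporting

Raster descriptive statistics use the population standard deviation
(the raster is the population). Regressions (LST on NDVI, ECI on LST,
ECI on NDVI) are ordinary least squares on a seeded random sample of
5,000 jointly valid pixels by default — mirroring scatter-plot practice
and keeping runtime flat — overridable to all pixels. The run manifest
records every output file with an MD5 hash, the seed and the
parameters, so a run is reproducible byte-for-byte from its config.

## Problem sizes used in the tests

The test suite exercises the full pipeline on 128×128 four-date bundles
(≈16k pixels, 600 reference points per date) and the unit layers on
grids between 2×2 and 100×100; property suites use 1,000+ random
vectors against brute-force oracles. These sizes were chosen as the
smallest at which the statistical assertions (accuracy ≥ 0.95, kappa
≥ 0.9, slope recovery within 10%) are stable across seeds.

## Known limitations

* The Gaussian classifier inherits MLC's sensitivity to training-sample
  quality and unimodality; no SVM/random-forest alternatives are
  provided.
* LST is single-channel with a fixed effective wavelength; no
  split-window or water-vapor correction.
* VCI inherits any long-term greening/browning trend present in the
  NDVI stack; it measures condition relative to the pixel's own
  history, not absolute drought.
* ECI is a ratio of rank-equalized layers: it is ordinal, not physical,
  and including water pixels (the default) inflates criticality along
  shorelines.
* Accuracy assessment is plain confusion-matrix inference; no
  area-adjusted (good-practice) estimators or kappa variance.
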