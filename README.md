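# forestpulse

Monitoring forest cover, vegetation condition and environmental
criticality from multi-date multispectral imagery.

`forestpulse` implements, as a tested R pipeline, the standard
Landsat-style forest-monitoring workflow used in land-change studies of
protected-area peripheries: supervised land-cover classification with
confusion-matrix accuracy assessment, change-detection cross-tabulation,
and the NDVI → emissivity → land-surface-temperature → VCI → ECI index
chain, together with a synthetic scene generator that provides known
ground truth for every stage. It is aimed at remote-sensing analysts and
method developers who want the full chain — from raw digital numbers to
drought and criticality classes — reproducible, seeded and unit-tested.

## The methods

**Classification.** Each of five land-cover classes (forest FC,
agriculture AG, built-up/settlements BS, water WB, other OT) is modelled
by a multivariate Gaussian fitted from training samples. A pixel vector
*X* is scored per class *c* by the weighted distance

D_c = ln(a_c) − ½ ln|Σ_c| − ½ (X − μ_c)ᵀ Σ_c⁻¹ (X − μ_c)

and labelled `argmax_c D_c` (equal priors a_c by default), followed by a
3×3 majority filter. Accuracy is assessed on stratified random reference
points via the confusion matrix: overall accuracy OA = Σx_ii / N,
producer's accuracy x_ii / column total, user's accuracy x_ii / row
total, and kappa

K = (N·Σx_ii − Σ x_i₊·x₊_i) / (N² − Σ x_i₊·x₊_i),

with an actionability flag at K ≥ 0.75. Change between dates is the
cross-tabulated transition area matrix, from which per-class gain, loss
and net change follow.

**Index chain.** NDVI = (NIR − RED)/(NIR + RED); proportion of vegetation
PV = ((NDVI − NDVI_min)/(NDVI_max − NDVI_min))²; emissivity
ε = 0.004·PV + 0.986; brightness temperature TB = K2 / ln(K1/L + 1) from
thermal radiance L; single-channel land surface temperature
LST = TB / (1 + (λ·TB/ρ)·ln ε) with ρ = h·c/k_B ≈ 1.438×10⁻² m·K,
reported in °C. The vegetation condition index
VCI = 100·(NDVI − NDVI_min)/(NDVI_max − NDVI_min) uses per-pixel extrema
across the multi-date stack and is binned into five drought classes; the
environmental criticality index ECI is the ratio of histogram-equalized
(1–255) LST to histogram-equalized NDVI.

## Worked example

```r
library(forestpulse)

cfg <- syntheticConfig(seed = 11)      # 128x128, 4 dates, 5 classes
res <- runPipeline(cfg, nDates = 4)

res$reports[[1]]
#> AccuracyReport: OA=0.977 kappa=0.950 (n=600, threshold 0.75 PASSED)
#>              FC    AG    BS    WB OT
#> producers 1.000 0.966 0.694 1.000  1
#> users     0.993 0.894 1.000 0.966  1

areaSummary(res$classified[[1]])
#>   class areaKm2 percent
#> 1    FC    9.83    71.0
#> 2    AG    2.16    15.6
#> 3    BS    0.58     4.2
#> 4    WB    0.67     4.8
#> 5    OT    0.60     4.4

gainLossNet(res$changes[[4]], "FC")    # endpoint pair, forest only
#>   class gainKm2 lossKm2  netKm2
#> 1    FC       0  0.7983 -0.7983

res$regressions[[1]]$lst_ndvi
#> RegressionResult: slope=-9.749 intercept=37.42 R2=0.9912 n=5000
```

The report says the maximum-likelihood map agrees with 97.7% of the 600
stratified reference points and clears the 0.75 kappa threshold; the
area table gives each class's share of the mapped area; the forest
gain/loss row shows the scripted forest conversion (−0.80 km² over the
full period, i.e. the configured 2%/step to agriculture plus 1%/step to
built-up); and the regression recovers the configured −10 K-per-NDVI
thermal coupling as a strong inverse LST–NDVI relationship.

A thin command-line wrapper is installed under
`inst/scripts/forestpulse.R`:

```sh
Rscript inst/scripts/forestpulse.R run --seed 1 --out out/
```

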