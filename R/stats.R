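## Descriptive raster statistics and the LST/NDVI/ECI regressions.

#' Descriptive statistics of an index raster
#'
#' Extrema, mean and population standard deviation over valid pixels
#' (whole-population semantics: the raster is the population, so the
#' divisor is n, not n - 1).
#'
#' @param r an [IndexRaster-class] or matrix.
#' @return A [RasterStats-class].
#' @export
rasterStats <- function(r) {
  v <- grabValues(r, NULL)
  v <- v[!is.na(v)]
  if (!length(v)) stopf("no valid pixels")
  m <- mean(v)
  new("RasterStats", min = min(v), max = max(v), mean = m,
      sd = sqrt(mean((v - m)^2)), nValid = length(v))
}

#' Ordinary least squares regression between two index rasters
#'
#' Regresses y on x over jointly valid pixels — all of them, or a seeded
#' random sample of `sampleN` (the default mirrors scatter-plot practice
#' of sampling the raster rather than using every pixel).
#'
#' @param y,x co-registered [IndexRaster-class] objects (or matrices).
#' @param sampleN number of pixels to sample (NULL = use all).
#' @param seed RNG seed for the sample.
#' @return A [RegressionResult-class] with slope, intercept and R-squared.
#' @export
regressIndices <- function(y, x, sampleN = 5000L, seed = 1L) {
  yv <- grabValues(y, NULL); xv <- grabValues(x, NULL)
  if (!identical(dim(yv), dim(xv))) stopf("rasters are not co-registered")
  ok <- which(!is.na(yv) & !is.na(xv))
  if (length(ok) < 3) stopf("need at least 3 jointly valid pixels")
  if (!is.null(sampleN) && length(ok) > sampleN) {
    set.seed(deriveSeed(seed, 6L))
    ok <- sample(ok, sampleN)
  }
  xs <- xv[ok]; ys <- yv[ok]
  if (stats::var(xs) == 0) stopf("x has zero variance; slope undefined")
  fit <- stats::lm(ys ~ xs)
  ## summary.lm warns on an exactly collinear fit; the R^2 is still valid
  rsq <- suppressWarnings(summary(fit)$r.squared)
  new("RegressionResult",
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      rSquared = rsq,
      nPoints = length(ok))
}
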