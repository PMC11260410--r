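#' @import methods
NULL

## ---------------------------------------------------------------------------
## SensorSpec
## ---------------------------------------------------------------------------

#' Sensor calibration specification
#'
#' Holds per-band radiometric calibration (gain/offset), the thermal
#' calibration constants K1 and K2 of the inverse Planck relation, the
#' effective thermal wavelength, and the mapping from band roles
#' (red, nir, thermal) to band indices.
#'
#' @slot sensorId one of "TM", "OLI_TIRS", "SYNTHETIC".
#' @slot bandRoles named integer vector with entries "red", "nir", "thermal".
#' @slot gain,offset numeric, one per band; radiance = gain * DN + offset.
#' @slot K1 thermal constant, W m-2 sr-1 um-1.
#' @slot K2 thermal constant, Kelvin.
#' @slot lambdaUm effective thermal wavelength in micrometers.
#' @export
setClass("SensorSpec",
  representation(sensorId = "character", bandRoles = "integer",
                 gain = "numeric", offset = "numeric",
                 K1 = "numeric", K2 = "numeric", lambdaUm = "numeric"))

setValidity("SensorSpec", function(object) {
  msg <- character()
  if (!object@sensorId %in% c("TM", "OLI_TIRS", "SYNTHETIC"))
    msg <- c(msg, "sensorId must be TM, OLI_TIRS or SYNTHETIC")
  if (!all(c("red", "nir", "thermal") %in% names(object@bandRoles)))
    msg <- c(msg, "bandRoles must name red, nir and thermal")
  if (anyDuplicated(object@bandRoles))
    msg <- c(msg, "bandRoles indices must be distinct")
  nb <- length(object@gain)
  if (length(object@offset) != nb)
    msg <- c(msg, "gain and offset must have equal length")
  if (any(object@bandRoles > nb) || any(object@bandRoles < 1L))
    msg <- c(msg, "bandRoles indices must be within the band count")
  if (object@K1 <= 0 || object@K2 <= 0) msg <- c(msg, "K1 and K2 must be > 0")
  if (object@lambdaUm < 10 || object@lambdaUm > 12.5)
    msg <- c(msg, "lambdaUm must lie in [10, 12.5]")
  if (length(msg)) msg else TRUE
})

#' Construct a SensorSpec
#'
#' @param sensorId sensor identifier.
#' @param bandRoles named integer vector ("red", "nir", "thermal").
#' @param gain,offset per-band calibration coefficients.
#' @param K1,K2 thermal calibration constants.
#' @param lambdaUm effective thermal wavelength (micrometers).
#' @return A [SensorSpec-class] object.
#' @export
sensorSpec <- function(sensorId, bandRoles, gain, offset, K1, K2, lambdaUm) {
  new("SensorSpec", sensorId = sensorId,
      bandRoles = vapply(bandRoles, as.integer, integer(1)),
      gain = as.numeric(gain), offset = as.numeric(offset),
      K1 = as.numeric(K1), K2 = as.numeric(K2),
      lambdaUm = as.numeric(lambdaUm))
}

#' Synthetic TM-like sensor specification
#'
#' Six reflective bands encoded with a 1/255 gain plus a thermal band using
#' the Landsat-5 TM band-6 calibration (gain 0.055158, offset 1.2378,
#' K1 = 607.76, K2 = 1260.56, lambda = 11.5 um), so the full DN -> radiance ->
#' brightness-temperature chain is exercised on generated scenes.
#'
#' @return A [SensorSpec-class].
#' @export
syntheticSensorSpec <- function() {
  sensorSpec("SYNTHETIC",
             bandRoles = c(red = 3L, nir = 4L, thermal = 7L),
             gain = c(rep(1 / 255, 6), 0.055158),
             offset = c(rep(0, 6), 1.2378),
             K1 = 607.76, K2 = 1260.56, lambdaUm = 11.5)
}

## ---------------------------------------------------------------------------
## Grid-shaped objects
## ---------------------------------------------------------------------------

#' Georeferenced grid (virtual base class)
#'
#' @slot geotransform GDAL-style affine vector
#'   (xmin, px, 0, ymax, 0, -py) mapping pixel to map coordinates.
#' @slot crs coordinate reference system identifier (e.g. "EPSG:32644").
#' @slot date acquisition date label.
#' @export
setClass("GeoGrid", representation("VIRTUAL",
  geotransform = "numeric", crs = "character", date = "character"))

setValidity("GeoGrid", function(object) {
  if (length(object@geotransform) != 6)
    return("geotransform must have 6 elements")
  ps <- gtPixelSize(object@geotransform)
  if (any(ps <= 0)) return("pixel size must be positive")
  TRUE
})

#' Multi-band scene
#'
#' A stack of co-registered bands (row x col x band array), a validity mask,
#' a processing-stage tag ("dn", "radiance" or "reflectance") and the sensor
#' calibration specification.
#'
#' @slot bands numeric array, dim = c(rows, cols, nBands).
#' @slot mask logical matrix, TRUE where the pixel is valid.
#' @slot stage processing stage of the band values.
#' @slot spec a [SensorSpec-class].
#' @export
setClass("RasterScene", contains = "GeoGrid",
  representation(bands = "array", mask = "matrix", stage = "character",
                 spec = "SensorSpec"))

setValidity("RasterScene", function(object) {
  d <- dim(object@bands)
  if (length(d) != 3) return("bands must be a 3-D array (rows, cols, bands)")
  if (!identical(dim(object@mask), d[1:2]))
    return("mask shape must equal band shape")
  if (length(object@spec@gain) != d[3])
    return("spec must carry calibration for every band")
  if (!object@stage %in% c("dn", "radiance", "reflectance"))
    return("stage must be dn, radiance or reflectance")
  TRUE
})

#' Construct a RasterScene
#'
#' @param bands rows x cols x bands numeric array.
#' @param mask logical validity matrix (default all valid).
#' @param stage processing stage tag.
#' @param spec a [SensorSpec-class].
#' @param geotransform affine geotransform (default 30 m grid at origin).
#' @param crs CRS identifier.
#' @param date acquisition date label.
#' @return A [RasterScene-class].
#' @export
rasterScene <- function(bands, mask = NULL, stage = "dn", spec,
                        geotransform = NULL, crs = "EPSG:32644", date = "") {
  d <- dim(bands)
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  if (is.null(geotransform)) geotransform <- makeGeotransform(30, nrow = d[1])
  new("RasterScene", bands = bands, mask = mask, stage = stage, spec = spec,
      geotransform = geotransform, crs = crs, date = as.character(date))
}

#' Categorical land-cover map
#'
#' @slot labels integer matrix over the legend, 0 = nodata.
#' @slot legend named integer vector mapping class code to label.
#' @export
setClass("ClassMap", contains = "GeoGrid",
  representation(labels = "matrix", legend = "integer"))

setValidity("ClassMap", function(object) {
  lab <- object@labels
  ok <- lab[!is.na(lab)]
  if (!all(ok %in% c(0L, object@legend)))
    return("labels must be 0 (nodata) or legend values")
  TRUE
})

#' Construct a ClassMap
#'
#' @param labels integer matrix (0 = nodata).
#' @param legend named integer legend, defaults to [lulcLegend()].
#' @param geotransform,crs,date georeferencing metadata.
#' @return A [ClassMap-class].
#' @export
classMap <- function(labels, legend = lulcLegend(), geotransform = NULL,
                     crs = "EPSG:32644", date = "") {
  storage.mode(labels) <- "integer"
  if (is.null(geotransform))
    geotransform <- makeGeotransform(30, nrow = nrow(labels))
  new("ClassMap", labels = labels, legend = legend,
      geotransform = geotransform, crs = crs, date = as.character(date))
}

#' Single-band index raster
#'
#' Continuous raster tagged with the index kind it holds (NDVI, PV,
#' EMISSIVITY, TB_K, LST_C, VCI, ECI or STRETCHED). Nodata pixels are NA.
#'
#' @slot values numeric matrix, NA = nodata.
#' @slot kind index kind tag.
#' @slot units measurement units ("" for dimensionless).
#' @export
setClass("IndexRaster", contains = "GeoGrid",
  representation(values = "matrix", kind = "character", units = "character"))

indexKinds <- c(NDVI = "", PV = "", EMISSIVITY = "", TB_K = "K",
                LST_C = "degC", VCI = "%", ECI = "", STRETCHED = "")

setValidity("IndexRaster", function(object) {
  if (!object@kind %in% names(indexKinds)) return("unknown index kind")
  v <- object@values[!is.na(object@values)]
  lim <- switch(object@kind,
    NDVI = c(-1, 1), PV = c(0, 1), VCI = c(0, 100),
    STRETCHED = c(1, 255), NULL)
  if (!is.null(lim) && length(v) &&
      (min(v) < lim[1] - 1e-9 || max(v) > lim[2] + 1e-9))
    return(sprintf("%s values outside [%g, %g]", object@kind, lim[1], lim[2]))
  if (object@kind == "LST_C" && length(v) && any(!is.finite(v)))
    return("LST_C must be finite on valid pixels")
  TRUE
})

#' Construct an IndexRaster
#'
#' @param values numeric matrix (NA = nodata).
#' @param kind index kind (see [IndexRaster-class]).
#' @param geotransform,crs,date georeferencing metadata.
#' @return An [IndexRaster-class].
#' @export
indexRaster <- function(values, kind, geotransform = NULL,
                        crs = "EPSG:32644", date = "") {
  if (is.null(geotransform))
    geotransform <- makeGeotransform(30, nrow = nrow(values))
  new("IndexRaster", values = values, kind = kind,
      units = unname(indexKinds[kind]),
      geotransform = geotransform, crs = crs, date = as.character(date))
}

## ---------------------------------------------------------------------------
## Tabular results
## ---------------------------------------------------------------------------

#' Confusion matrix (map rows x reference columns)
#'
#' @slot counts k x k nonnegative integer matrix; rows are the classified map
#'   label, columns the reference label.
#' @slot classLabels ordered class codes.
#' @export
setClass("ConfusionMatrix",
  representation(counts = "matrix", classLabels = "character"))

setValidity("ConfusionMatrix", function(object) {
  cnt <- object@counts
  if (nrow(cnt) != ncol(cnt)) return("counts must be square")
  if (any(cnt < 0)) return("counts must be nonnegative")
  if (sum(cnt) <= 0) return("total count must be positive")
  if (length(object@classLabels) != nrow(cnt))
    return("classLabels length must match matrix order")
  TRUE
})

#' Construct a ConfusionMatrix
#'
#' @param counts square count matrix, rows = map label, columns = reference.
#' @param classLabels class codes in row/column order (defaults to the
#'   legend codes, or dimnames of `counts`).
#' @return A [ConfusionMatrix-class].
#' @export
confusionMatrix <- function(counts, classLabels = NULL) {
  counts <- as.matrix(counts)
  if (is.null(classLabels)) {
    classLabels <- rownames(counts)
    if (is.null(classLabels))
      classLabels <- names(lulcLegend())[seq_len(nrow(counts))]
  }
  dimnames(counts) <- list(map = classLabels, reference = classLabels)
  new("ConfusionMatrix", counts = counts, classLabels = classLabels)
}

#' Accuracy assessment report
#'
#' @slot overallAccuracy fraction of correctly labelled reference points.
#' @slot producersAccuracy,usersAccuracy named per-class fractions (NA where
#'   the column/row total is zero).
#' @slot kappa chance-corrected agreement.
#' @slot nPoints number of reference points used.
#' @slot threshold kappa threshold for actionability.
#' @slot passesThreshold TRUE when kappa >= threshold.
#' @export
setClass("AccuracyReport",
  representation(overallAccuracy = "numeric", producersAccuracy = "numeric",
                 usersAccuracy = "numeric", kappa = "numeric",
                 nPoints = "integer", threshold = "numeric",
                 passesThreshold = "logical"))

#' Change (transition) area matrix between two dates
#'
#' @slot areasKm2 k x k area matrix; cell (i, j) is the area classified i at
#'   date 1 and j at date 2, in square kilometers.
#' @slot datePair the two date labels.
#' @slot pixelAreaKm2 area of one pixel in square kilometers.
#' @slot classLabels ordered class codes.
#' @export
setClass("ChangeMatrix",
  representation(areasKm2 = "matrix", datePair = "character",
                 pixelAreaKm2 = "numeric", classLabels = "character"))

setValidity("ChangeMatrix", function(object) {
  if (nrow(object@areasKm2) != ncol(object@areasKm2))
    return("areasKm2 must be square")
  if (any(object@areasKm2 < 0)) return("areas must be nonnegative")
  TRUE
})

#' Gaussian class-conditional model for maximum-likelihood classification
#'
#' @slot means list of per-class mean vectors.
#' @slot covs list of per-class covariance matrices.
#' @slot priors named prior probabilities summing to one.
#' @slot bandCount feature-vector length.
#' @export
setClass("GaussianClassModel",
  representation(means = "list", covs = "list", priors = "numeric",
                 bandCount = "integer"))

setValidity("GaussianClassModel", function(object) {
  if (abs(sum(object@priors) - 1) > 1e-9) return("priors must sum to 1")
  if (any(object@priors <= 0)) return("priors must be positive")
  if (!identical(names(object@means), names(object@covs)))
    return("means and covs must name the same classes")
  TRUE
})

#' Ordinary-least-squares regression result
#'
#' @slot slope,intercept fitted coefficients of y on x.
#' @slot rSquared coefficient of determination.
#' @slot nPoints number of pixel pairs used.
#' @export
setClass("RegressionResult",
  representation(slope = "numeric", intercept = "numeric",
                 rSquared = "numeric", nPoints = "integer"))

#' Descriptive raster statistics
#'
#' @slot min,max,mean,sd summary values over valid pixels (population
#'   standard deviation).
#' @slot nValid number of valid pixels.
#' @export
setClass("RasterStats",
  representation(min = "numeric", max = "numeric", mean = "numeric",
                 sd = "numeric", nValid = "integer"))

## ---------------------------------------------------------------------------
## Synthetic configuration and bundle
## ---------------------------------------------------------------------------

#' Configuration for the synthetic scene generator
#'
#' @slot gridRows,gridCols grid size in pixels.
#' @slot pixelSizeM pixel size in meters.
#' @slot seed base RNG seed.
#' @slot classFractions named target area fractions over the 5-class legend.
#' @slot patchScale mean patch diameter in pixels.
#' @slot bandMeans class x band matrix of mean reflectances in [0, 1].
#' @slot bandCov per-class covariance matrices (list).
#' @slot tbBaseK,tbNdviSlopeK,tbNoiseSdK brightness-temperature model:
#'   TB = base + slope * NDVI + N(0, noise).
#' @slot transitionRates data.frame(from, to, rate) of per-step conversions.
#' @slot nodataBorderPx width of the nodata border.
#' @slot spec the [SensorSpec-class] used to encode scenes to DN.
#' @export
setClass("SyntheticConfig",
  representation(gridRows = "integer", gridCols = "integer",
                 pixelSizeM = "numeric", seed = "integer",
                 classFractions = "numeric", patchScale = "numeric",
                 bandMeans = "matrix", bandCov = "list",
                 tbBaseK = "numeric", tbNdviSlopeK = "numeric",
                 tbNoiseSdK = "numeric", transitionRates = "data.frame",
                 nodataBorderPx = "integer", spec = "SensorSpec"))

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (object@gridRows < 16L || object@gridCols < 16L)
    msg <- c(msg, "grid dimensions must be >= 16")
  if (abs(sum(object@classFractions) - 1) > 1e-9)
    msg <- c(msg, "class fractions must sum to 1")
  if (any(object@classFractions < 0))
    msg <- c(msg, "class fractions must be nonnegative")
  if (object@patchScale <= 0) msg <- c(msg, "patchScale must be positive")
  for (cl in names(object@bandCov)) {
    cv <- object@bandCov[[cl]]
    if (!isSymmetric(unname(cv)) ||
        (any(diag(cv) > 0) && min(eigen(cv, symmetric = TRUE,
                                        only.values = TRUE)$values) < -1e-12))
      msg <- c(msg, sprintf("covariance for class %s not symmetric PSD", cl))
  }
  tr <- object@transitionRates
  if (nrow(tr) && (any(tr$rate < 0) || any(tr$rate > 1)))
    msg <- c(msg, "transition rates must lie in [0, 1]")
  if (object@nodataBorderPx < 0L)
    msg <- c(msg, "nodataBorderPx must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Dated scenes plus matching ground-truth maps
#'
#' @slot scenes list of [RasterScene-class], one per date.
#' @slot truthMaps list of [ClassMap-class], same dates.
#' @slot config the generating [SyntheticConfig-class].
#' @export
setClass("TruthBundle",
  representation(scenes = "list", truthMaps = "list",
                 config = "SyntheticConfig"))

setValidity("TruthBundle", function(object) {
  if (length(object@scenes) != length(object@truthMaps))
    return("scenes and truthMaps must have equal length")
  TRUE
})

## ---------------------------------------------------------------------------
## Accessors
## ---------------------------------------------------------------------------

#' @describeIn RasterScene-class band array accessor
#' @param x object.
#' @export
sceneBands <- function(x) x@bands

#' @describeIn RasterScene-class validity-mask accessor
#' @export
sceneMask <- function(x) x@mask

#' @describeIn RasterScene-class processing-stage accessor
#' @export
sceneStage <- function(x) x@stage

#' @describeIn RasterScene-class sensor-spec accessor
#' @export
sceneSpec <- function(x) x@spec

#' @describeIn ClassMap-class label-matrix accessor
#' @param x object.
#' @export
mapLabels <- function(x) x@labels

#' @describeIn ClassMap-class legend accessor
#' @export
mapLegend <- function(x) x@legend

#' @describeIn IndexRaster-class value-matrix accessor
#' @param x object.
#' @export
indexValues <- function(x) x@values

#' @describeIn IndexRaster-class kind accessor
#' @export
indexKind <- function(x) x@kind

#' @describeIn ConfusionMatrix-class count-matrix accessor
#' @param x object.
#' @export
cmCounts <- function(x) x@counts

#' @describeIn ChangeMatrix-class area-matrix accessor
#' @param x object.
#' @export
changeAreas <- function(x) x@areasKm2

#' Geotransform accessor
#' @param x a GeoGrid-derived object.
#' @return numeric(6) affine geotransform.
#' @export
geoTransform <- function(x) x@geotransform

#' CRS identifier accessor
#' @param x a GeoGrid-derived object.
#' @export
crsId <- function(x) x@crs

#' Date label accessor
#' @param x a GeoGrid-derived object.
#' @export
gridDate <- function(x) x@date

#' Pixel area in square kilometers
#' @param x a GeoGrid-derived object.
#' @export
pixelAreaKm2 <- function(x) {
  ps <- gtPixelSize(x@geotransform)
  ps[1] * ps[2] / 1e6
}

#' @describeIn TruthBundle-class scene-list accessor
#' @param x object.
#' @export
bundleScenes <- function(x) x@scenes

#' @describeIn TruthBundle-class truth-map-list accessor
#' @export
bundleTruth <- function(x) x@truthMaps

#' @describeIn TruthBundle-class config accessor
#' @export
bundleConfig <- function(x) x@config

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "RasterScene", function(object) {
  d <- dim(object@bands)
  cat(sprintf("RasterScene %dx%d, %d band(s), stage=%s, date=%s, %s\n",
              d[1], d[2], d[3], object@stage,
              ifelse(nzchar(object@date), object@date, "<unset>"),
              object@crs))
  cat(sprintf("  valid pixels: %d/%d\n", sum(object@mask), d[1] * d[2]))
})

setMethod("show", "ClassMap", function(object) {
  cat(sprintf("ClassMap %dx%d, date=%s\n", nrow(object@labels),
              ncol(object@labels),
              ifelse(nzchar(object@date), object@date, "<unset>")))
  tab <- table(factor(object@labels[object@labels > 0],
                      levels = object@legend,
                      labels = names(object@legend)))
  print(tab)
})

setMethod("show", "IndexRaster", function(object) {
  v <- object@values[!is.na(object@values)]
  cat(sprintf("IndexRaster[%s] %dx%d, range [%.4g, %.4g], units '%s'\n",
              object@kind, nrow(object@values), ncol(object@values),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA,
              object@units))
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (rows = map, columns = reference)\n")
  print(object@counts)
})

setMethod("show", "AccuracyReport", function(object) {
  cat(sprintf("AccuracyReport: OA=%.3f kappa=%.3f (n=%d, threshold %.2f %s)\n",
              object@overallAccuracy, object@kappa, object@nPoints,
              object@threshold,
              if (object@passesThreshold) "PASSED" else "NOT PASSED"))
  print(rbind(producers = round(object@producersAccuracy, 3),
              users = round(object@usersAccuracy, 3)))
})

setMethod("show", "ChangeMatrix", function(object) {
  cat(sprintf("ChangeMatrix %s -> %s (km2)\n",
              object@datePair[1], object@datePair[2]))
  print(round(object@areasKm2, 3))
})

setMethod("show", "RegressionResult", function(object) {
  cat(sprintf("RegressionResult: slope=%.4g intercept=%.4g R2=%.4f n=%d\n",
              object@slope, object@intercept, object@rSquared,
              object@nPoints))
})

setMethod("show", "RasterStats", function(object) {
  cat(sprintf("RasterStats: min=%.4g max=%.4g mean=%.4g sd=%.4g n=%d\n",
              object@min, object@max, object@mean, object@sd, object@nValid))
})

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf("SyntheticConfig %dx%d px, %g m, seed %d, %d date-step rule(s)\n",
              object@gridRows, object@gridCols, object@pixelSizeM,
              object@seed, nrow(object@transitionRates)))
  print(round(object@classFractions, 3))
})

setMethod("show", "TruthBundle", function(object) {
  cat(sprintf("TruthBundle with %d date(s): %s\n", length(object@scenes),
              paste(vapply(object@scenes, gridDate, ""), collapse = ", ")))
})
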