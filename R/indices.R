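## Vegetation indices: NDVI and density classes, vegetation condition
## index (VCI) with drought classes, histogram-equalization stretch and
## the environmental criticality index (ECI).

grabValues <- function(x, kind = NULL) {
  if (is(x, "IndexRaster")) {
    if (!is.null(kind) && indexKind(x) != kind)
      stopf("expected an index raster of kind %s, got %s", kind,
            indexKind(x))
    x@values
  } else if (is.matrix(x)) {
    if (!is.null(kind) && kind != "NDVI" && kind != "ANY")
      stopf("expected an IndexRaster of kind %s", kind)
    x
  } else stopf("expected a matrix or IndexRaster")
}

grabGeo <- function(x, fallbackNrow) {
  if (is(x, "GeoGrid"))
    list(gt = geoTransform(x), crs = crsId(x), date = gridDate(x))
  else
    list(gt = makeGeotransform(30, nrow = fallbackNrow), crs = "EPSG:32644",
         date = "")
}

#' Normalized difference vegetation index
#'
#' NDVI = (NIR - RED) / (NIR + RED), clamped to [-1, 1]; pixels where
#' NIR + RED = 0 (or either input is nodata) become nodata.
#'
#' @param nir,red near-infrared and red band matrices (nonnegative,
#'   calibrated values) of equal shape.
#' @param geotransform,crs,date georeferencing metadata for the result.
#' @return An [IndexRaster-class] of kind NDVI.
#' @export
ndvi <- function(nir, red, geotransform = NULL, crs = "EPSG:32644",
                 date = "") {
  if (!identical(dim(nir), dim(red))) stopf("NIR and RED shapes differ")
  s <- nir + red
  v <- ifelse(!is.na(s) & s > 0, (nir - red) / s, NA_real_)
  v <- pmin(pmax(v, -1), 1)
  if (is.null(geotransform))
    geotransform <- makeGeotransform(30, nrow = nrow(nir))
  indexRaster(v, "NDVI", geotransform = geotransform, crs = crs, date = date)
}

#' NDVI of a calibrated scene
#'
#' Convenience wrapper pulling the red/nir bands named by the scene's
#' sensor spec; nodata pixels propagate.
#'
#' @param scene a calibrated [RasterScene-class].
#' @return An [IndexRaster-class] of kind NDVI.
#' @export
sceneNdvi <- function(scene) {
  roles <- scene@spec@bandRoles
  nir <- scene@bands[, , roles[["nir"]]]
  red <- scene@bands[, , roles[["red"]]]
  nir[!scene@mask] <- NA; red[!scene@mask] <- NA
  ndvi(nir, red, geotransform = scene@geotransform, crs = scene@crs,
       date = scene@date)
}

#' Classify NDVI into vegetation density classes
#'
#' Four classes: non-vegetation (NDVI < 0), low density [0, 0.2),
#' moderate density [0.2, 0.5] and high density (> 0.5).
#'
#' @param x an [IndexRaster-class] of kind NDVI.
#' @return A [ClassMap-class] with legend nonveg/low/moderate/high.
#' @export
classifyNdvi <- function(x) {
  v <- grabValues(x, "NDVI")
  lab <- 1L + (v >= 0) + (v >= 0.2) + (v > 0.5)
  lab[is.na(v)] <- 0L
  geo <- grabGeo(x, nrow(v))
  classMap(matrix(as.integer(lab), nrow(v), ncol(v)),
           legend = c(nonveg = 1L, low = 2L, moderate = 3L, high = 4L),
           geotransform = geo$gt, crs = geo$crs, date = geo$date)
}

#' Proportion of vegetation
#'
#' PV = ((NDVI - NDVImin) / (NDVImax - NDVImin))^2 with the extrema taken
#' over the valid pixels of this scene.
#'
#' @param x an [IndexRaster-class] of kind NDVI.
#' @return An [IndexRaster-class] of kind PV.
#' @export
proportionVegetation <- function(x) {
  v <- grabValues(x, "NDVI")
  rng <- range(v, na.rm = TRUE)
  if (!is.finite(rng[1]) || rng[2] <= rng[1])
    stopf("NDVI range is degenerate; PV is undefined")
  pv <- ((v - rng[1]) / (rng[2] - rng[1]))^2
  geo <- grabGeo(x, nrow(v))
  indexRaster(pv, "PV", geotransform = geo$gt, crs = geo$crs,
              date = geo$date)
}

#' Vegetation condition index across a multi-date NDVI stack
#'
#' Per pixel and date, VCI = 100 * (NDVI - NDVImin) / (NDVImax - NDVImin)
#' with min/max taken per pixel across the stack: 0 marks the pixel's
#' historical worst (extreme drought), 100 its best condition. Pixels with
#' a degenerate stack range (max = min) become nodata.
#'
#' @param ndviStack list of co-registered [IndexRaster-class] NDVI layers
#'   (>= 2).
#' @return List of [IndexRaster-class] VCI layers, one per input date.
#' @export
vci <- function(ndviStack) {
  if (length(ndviStack) < 2) stopf("VCI needs at least 2 NDVI layers")
  vals <- lapply(ndviStack, grabValues, kind = "NDVI")
  d <- dim(vals[[1]])
  if (!all(vapply(vals, function(v) identical(dim(v), d), logical(1))))
    stopf("NDVI layers are not co-registered")
  arr <- simplify2array(vals)
  lo <- apply(arr, c(1, 2), min)
  hi <- apply(arr, c(1, 2), max)
  span <- hi - lo
  lapply(seq_along(vals), function(t) {
    v <- 100 * (vals[[t]] - lo) / span
    v[!is.finite(v) | span <= 0] <- NA_real_
    geo <- grabGeo(ndviStack[[t]], d[1])
    indexRaster(pmin(pmax(v, 0), 100), "VCI", geotransform = geo$gt,
                crs = geo$crs, date = geo$date)
  })
}

#' Classify VCI into drought severity classes
#'
#' Five classes: non drought [50, 100], mild [30, 50), moderate [20, 30),
#' severe [10, 20), extreme [0, 10).
#'
#' @param x an [IndexRaster-class] of kind VCI.
#' @return A [ClassMap-class] with legend non/mild/moderate/severe/extreme.
#' @export
classifyVci <- function(x) {
  v <- grabValues(x, "VCI")
  lab <- 1L + (v < 50) + (v < 30) + (v < 20) + (v < 10)
  lab[is.na(v)] <- 0L
  geo <- grabGeo(x, nrow(v))
  classMap(matrix(as.integer(lab), nrow(v), ncol(v)),
           legend = c(non = 1L, mild = 2L, moderate = 3L, severe = 4L,
                      extreme = 5L),
           geotransform = geo$gt, crs = geo$crs, date = geo$date)
}

#' Histogram-equalization stretch
#'
#' Rank-based equalization mapping value v to
#' round(lo + (hi - lo) * (rank(v) - 1) / (n - 1)) with average ranks for
#' ties; the output is integer-valued in [lo, hi] and monotone
#' non-decreasing in the input. A constant grid maps to the midpoint.
#'
#' @param x matrix or [IndexRaster-class].
#' @param lo,hi output range (default 1..255).
#' @return An [IndexRaster-class] of kind STRETCHED.
#' @export
histogramStretch <- function(x, lo = 1, hi = 255) {
  v <- grabValues(x, NULL)
  valid <- which(!is.na(v))
  n <- length(valid)
  if (n == 0) stopf("no valid pixels to stretch")
  out <- matrix(NA_real_, nrow(v), ncol(v))
  if (n == 1 || max(v[valid]) == min(v[valid])) {
    out[valid] <- round((lo + hi) / 2)
  } else {
    r <- rank(v[valid], ties.method = "average")
    out[valid] <- round(lo + (hi - lo) * (r - 1) / (n - 1))
  }
  geo <- grabGeo(x, nrow(v))
  indexRaster(out, "STRETCHED", geotransform = geo$gt, crs = geo$crs,
              date = geo$date)
}

#' Environmental criticality index
#'
#' ECI = stretched(LST) / stretched(NDVI), both histogram-equalized to
#' 1..255 over their valid pixels, so ECI grows with thermal rank and
#' shrinks with greenness rank; the stretch floor of 1 keeps the ratio
#' defined everywhere. Water/non-vegetation pixels are not masked by
#' default; pass `maskNonveg = TRUE` to exclude NDVI < 0 pixels.
#'
#' @param lstR [IndexRaster-class] of kind LST_C.
#' @param ndviR co-registered [IndexRaster-class] of kind NDVI.
#' @param maskNonveg exclude pixels with NDVI < 0 before stretching.
#' @return An [IndexRaster-class] of kind ECI.
#' @export
eci <- function(lstR, ndviR, maskNonveg = FALSE) {
  lv <- grabValues(lstR, "LST_C")
  nv <- grabValues(ndviR, "NDVI")
  if (!identical(dim(lv), dim(nv))) stopf("LST and NDVI are not aligned")
  if (maskNonveg) {
    drop <- !is.na(nv) & nv < 0
    lv[drop] <- NA_real_; nv[drop] <- NA_real_
  }
  joint <- is.na(lv) | is.na(nv)
  lv[joint] <- NA_real_; nv[joint] <- NA_real_
  sl <- indexValues(histogramStretch(lv))
  sn <- indexValues(histogramStretch(nv))
  geo <- grabGeo(lstR, nrow(lv))
  indexRaster(sl / sn, "ECI", geotransform = geo$gt, crs = geo$crs,
              date = geo$date)
}

#' Classify ECI into criticality classes
#'
#' Low/medium/high by tercile breaks over valid pixels by default, or by
#' supplied fixed breaks. A degenerate (constant) grid maps to medium.
#'
#' @param x an [IndexRaster-class] of kind ECI.
#' @param breaks optional numeric(2) fixed breaks (low <= b1 < medium <=
#'   b2 < high).
#' @return A [ClassMap-class] with legend low/medium/high.
#' @export
classifyEci <- function(x, breaks = NULL) {
  v <- grabValues(x, "ECI")
  valid <- !is.na(v)
  geo <- grabGeo(x, nrow(v))
  if (is.null(breaks)) {
    vv <- v[valid]
    if (length(unique(vv)) == 1L) {
      lab <- matrix(ifelse(valid, 2L, 0L), nrow(v), ncol(v))
      return(classMap(lab, legend = c(low = 1L, medium = 2L, high = 3L),
                      geotransform = geo$gt, crs = geo$crs,
                      date = geo$date))
    }
    breaks <- stats::quantile(vv, c(1 / 3, 2 / 3), names = FALSE)
  }
  lab <- 1L + (v > breaks[1]) + (v > breaks[2])
  lab[!valid] <- 0L
  classMap(matrix(as.integer(lab), nrow(v), ncol(v)),
           legend = c(low = 1L, medium = 2L, high = 3L),
           geotransform = geo$gt, crs = geo$crs, date = geo$date)
}
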