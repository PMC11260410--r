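## Radiometric calibration, dark-object subtraction, AOI clipping and
## nearest-neighbor resampling.

#' Convert digital numbers to radiance
#'
#' Applies the per-band affine calibration L = gain * DN + offset from the
#' scene's sensor spec. Calibration is order-preserving per band and the
#' validity mask is untouched.
#'
#' @param scene a [RasterScene-class] at stage "dn".
#' @return The calibrated scene at stage "radiance".
#' @export
dnToRadiance <- function(scene) {
  if (scene@stage != "dn")
    stopf("scene stage is '%s', expected 'dn'", scene@stage)
  spec <- scene@spec
  nb <- dim(scene@bands)[3]
  if (length(spec@gain) < nb || anyNA(spec@gain[seq_len(nb)]) ||
      anyNA(spec@offset[seq_len(nb)]))
    stopf("missing calibration coefficients for some band")
  out <- scene
  for (b in seq_len(nb))
    out@bands[, , b] <- spec@gain[b] * scene@bands[, , b] + spec@offset[b]
  out@stage <- "radiance"
  out
}

#' Dark-object subtraction
#'
#' First-order atmospheric (haze) correction: per reflective band, the
#' dark-object value — the 1st percentile of valid pixels, robust to
#' single-pixel outliers — is subtracted and results clipped at zero. The
#' thermal band is untouched (DOS is a reflective-band correction).
#'
#' @param scene a [RasterScene-class] at stage "radiance" or "reflectance".
#' @param probs dark-object percentile (default 0.01).
#' @return The corrected scene.
#' @export
dosCorrection <- function(scene, probs = 0.01) {
  if (!scene@stage %in% c("radiance", "reflectance"))
    stopf("DOS expects a calibrated scene (radiance/reflectance), got '%s'",
          scene@stage)
  if (!any(scene@mask)) stopf("scene is entirely nodata")
  thermal <- scene@spec@bandRoles[["thermal"]]
  out <- scene
  for (b in seq_len(dim(scene@bands)[3])) {
    if (!is.na(thermal) && b == thermal) next
    v <- scene@bands[, , b]
    dark <- stats::quantile(v[scene@mask], probs, names = FALSE)
    out@bands[, , b] <- pmax(v - dark, 0)
  }
  out
}

#' Clip a scene to an area of interest
#'
#' Crops the grid to the polygon's bounding box (snapped outward to the
#' pixel grid) and masks pixels whose centers fall outside the polygon.
#' Surviving pixel values are never altered.
#'
#' @param scene a [RasterScene-class].
#' @param aoi two-column matrix of polygon vertices (x, y) in the scene CRS.
#' @return The clipped scene.
#' @export
clipToAoi <- function(scene, aoi) {
  aoi <- as.matrix(aoi)
  gt <- scene@geotransform
  d <- dim(scene@bands)
  ps <- gtPixelSize(gt)
  xmin <- gt[1]; ymax <- gt[4]
  xmax <- xmin + d[2] * ps[1]; ymin <- ymax - d[1] * ps[2]
  bx <- range(aoi[, 1]); by <- range(aoi[, 2])
  if (bx[2] <= xmin || bx[1] >= xmax || by[2] <= ymin || by[1] >= ymax)
    stopf("AOI does not intersect the scene extent")
  c0 <- max(1L, floor((bx[1] - xmin) / ps[1]) + 1L)
  c1 <- min(d[2], ceiling((bx[2] - xmin) / ps[1]))
  r0 <- max(1L, floor((ymax - by[2]) / ps[2]) + 1L)
  r1 <- min(d[1], ceiling((ymax - by[1]) / ps[2]))
  rows <- r0:r1; cols <- c0:c1
  out <- scene
  out@bands <- scene@bands[rows, cols, , drop = FALSE]
  out@mask <- scene@mask[rows, cols, drop = FALSE]
  out@geotransform <- c(xmin + (c0 - 1L) * ps[1], ps[1], 0,
                        ymax - (r0 - 1L) * ps[2], 0, -ps[2])
  rc <- expand.grid(row = seq_along(rows), col = seq_along(cols))
  ctr <- pixelCenters(out@geotransform, rc$row, rc$col)
  inside <- matrix(FALSE, length(rows), length(cols))
  inside[cbind(rc$row, rc$col)] <- pointsInPolygon(ctr, aoi)
  out@mask <- out@mask & inside
  out
}

nearestIndexMap <- function(nSrc, srcSize, targetSize) {
  extent <- nSrc * srcSize
  nOut <- max(1L, as.integer(ceiling(extent / targetSize - 1e-9)))
  centers <- (seq_len(nOut) - 0.5) * targetSize
  pmin(pmax(ceiling(centers / srcSize), 1L), nSrc)
}

#' Nearest-neighbor resampling
#'
#' Resamples a grid to a new pixel size over the same extent. Each output
#' pixel takes the value of the source pixel containing its center, so no
#' new values are introduced (safe for categorical maps).
#'
#' @param x a [RasterScene-class], [ClassMap-class] or [IndexRaster-class].
#' @param targetPixelSizeM target pixel size in meters.
#' @return Object of the same class on the resampled grid.
#' @export
setGeneric("resampleNearest", function(x, targetPixelSizeM)
  standardGeneric("resampleNearest"))

resampleGt <- function(gt, targetPixelSizeM) {
  c(gt[1], targetPixelSizeM, 0, gt[4], 0, -targetPixelSizeM)
}

checkTargetSize <- function(targetPixelSizeM) {
  if (!is.numeric(targetPixelSizeM) || targetPixelSizeM <= 0)
    stopf("target pixel size must be positive")
}

#' @describeIn resampleNearest scene method (bands and mask resampled).
#' @export
setMethod("resampleNearest", "RasterScene", function(x, targetPixelSizeM) {
  checkTargetSize(targetPixelSizeM)
  ps <- gtPixelSize(x@geotransform)
  ri <- nearestIndexMap(nrow(x@mask), ps[2], targetPixelSizeM)
  ci <- nearestIndexMap(ncol(x@mask), ps[1], targetPixelSizeM)
  nb <- dim(x@bands)[3]
  bands <- array(0, dim = c(length(ri), length(ci), nb))
  for (b in seq_len(nb)) bands[, , b] <- x@bands[ri, ci, b]
  out <- x
  out@bands <- bands
  out@mask <- x@mask[ri, ci, drop = FALSE]
  out@geotransform <- resampleGt(x@geotransform, targetPixelSizeM)
  out
})

#' @describeIn resampleNearest class-map method (labels resampled).
#' @export
setMethod("resampleNearest", "ClassMap", function(x, targetPixelSizeM) {
  checkTargetSize(targetPixelSizeM)
  ps <- gtPixelSize(x@geotransform)
  ri <- nearestIndexMap(nrow(x@labels), ps[2], targetPixelSizeM)
  ci <- nearestIndexMap(ncol(x@labels), ps[1], targetPixelSizeM)
  out <- x
  out@labels <- x@labels[ri, ci, drop = FALSE]
  out@geotransform <- resampleGt(x@geotransform, targetPixelSizeM)
  out
})

#' @describeIn resampleNearest index-raster method (values resampled).
#' @export
setMethod("resampleNearest", "IndexRaster", function(x, targetPixelSizeM) {
  checkTargetSize(targetPixelSizeM)
  ps <- gtPixelSize(x@geotransform)
  ri <- nearestIndexMap(nrow(x@values), ps[2], targetPixelSizeM)
  ci <- nearestIndexMap(ncol(x@values), ps[1], targetPixelSizeM)
  out <- x
  out@values <- x@values[ri, ci, drop = FALSE]
  out@geotransform <- resampleGt(x@geotransform, targetPixelSizeM)
  out
})
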