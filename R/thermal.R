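## Thermal retrieval: emissivity from the proportion of vegetation,
## brightness temperature from thermal radiance (inverse Planck), and the
## single-channel emissivity-corrected land surface temperature.

#' Second radiation constant h*c/sigma
#'
#' Ratio of the Planck constant times the speed of light to the Boltzmann
#' constant, in meter-Kelvin. With CODATA constants this is
#' 1.4388e-2 m K; the single-channel LST formula uses its rounded value
#' 1.438e-2 m K by default.
#'
#' @param h Planck constant (J s).
#' @param c speed of light (m/s).
#' @param sigma Boltzmann constant (J/K).
#' @return h * c / sigma in m K.
#' @export
thermalRho <- function(h = 6.626e-34, c = 2.998e8, sigma = 1.38e-23) {
  h * c / sigma
}

#' Land surface emissivity from the proportion of vegetation
#'
#' Linear mixing model epsilon = m * PV + n; the default coefficients
#' m = 0.004 and n = 0.986 absorb the soil and vegetation endmember
#' emissivities, so a fully non-vegetated pixel (PV = 0) has
#' epsilon = 0.986 and a fully vegetated one 0.990.
#'
#' @param pv an [IndexRaster-class] of kind PV (or matrix in [0, 1]).
#' @param m,n mixing coefficients.
#' @return An [IndexRaster-class] of kind EMISSIVITY.
#' @export
emissivity <- function(pv, m = 0.004, n = 0.986) {
  v <- grabValues(pv, if (is(pv, "IndexRaster")) "PV" else NULL)
  geo <- grabGeo(pv, nrow(v))
  indexRaster(m * v + n, "EMISSIVITY", geotransform = geo$gt,
              crs = geo$crs, date = geo$date)
}

#' Brightness temperature from thermal radiance
#'
#' Inverse Planck relation TB = K2 / ln(K1 / L + 1) in Kelvin; pixels with
#' nonpositive radiance become nodata.
#'
#' @param thermalRadiance matrix of spectral radiance
#'   (W m-2 sr-1 um-1), or an [IndexRaster-class].
#' @param K1,K2 thermal calibration constants.
#' @param geotransform,crs,date georeferencing for matrix input.
#' @return An [IndexRaster-class] of kind TB_K.
#' @export
brightnessTemperature <- function(thermalRadiance, K1, K2,
                                  geotransform = NULL, crs = "EPSG:32644",
                                  date = "") {
  v <- if (is(thermalRadiance, "IndexRaster")) thermalRadiance@values
       else thermalRadiance
  tb <- matrix(NA_real_, nrow(v), ncol(v))
  pos <- which(!is.na(v) & v > 0)
  tb[pos] <- K2 / log(K1 / v[pos] + 1)
  geo <- if (is(thermalRadiance, "GeoGrid"))
    grabGeo(thermalRadiance, nrow(v))
  else list(gt = if (is.null(geotransform))
                   makeGeotransform(30, nrow = nrow(v)) else geotransform,
            crs = crs, date = date)
  indexRaster(tb, "TB_K", geotransform = geo$gt, crs = geo$crs,
              date = geo$date)
}

#' Brightness temperature of a calibrated scene's thermal band
#'
#' @param scene a [RasterScene-class] at stage "radiance".
#' @return An [IndexRaster-class] of kind TB_K.
#' @export
sceneBrightnessTemperature <- function(scene) {
  if (scene@stage == "dn")
    stopf("calibrate the scene to radiance before computing TB")
  spec <- scene@spec
  L <- scene@bands[, , spec@bandRoles[["thermal"]]]
  L[!scene@mask] <- NA
  brightnessTemperature(L, spec@K1, spec@K2,
                        geotransform = scene@geotransform, crs = scene@crs,
                        date = scene@date)
}

#' Emissivity-corrected land surface temperature
#'
#' Single-channel correction
#' LST_K = TB / (1 + (lambda * TB / rho) * ln(epsilon)) with lambda the
#' effective thermal wavelength (meters) and rho the second radiation
#' constant (m K); the result is returned in degrees Celsius
#' (LST_K - 273.15). In the blackbody limit epsilon = 1 the correction
#' vanishes and LST_K equals TB.
#'
#' @param tb an [IndexRaster-class] of kind TB_K.
#' @param eps an [IndexRaster-class] of kind EMISSIVITY (values in (0, 1]).
#' @param lambdaUm effective thermal wavelength in micrometers.
#' @param rho second radiation constant in m K.
#' @return An [IndexRaster-class] of kind LST_C.
#' @export
landSurfaceTemperature <- function(tb, eps, lambdaUm, rho = 1.438e-2) {
  tbv <- grabValues(tb, "TB_K")
  ev <- grabValues(eps, if (is(eps, "IndexRaster")) "EMISSIVITY" else NULL)
  if (!identical(dim(tbv), dim(ev))) stopf("TB and emissivity not aligned")
  ev <- ifelse(!is.na(ev) & ev > 0, ev, NA_real_)
  lambdaM <- lambdaUm * 1e-6
  lstK <- tbv / (1 + (lambdaM * tbv / rho) * log(ev))
  geo <- grabGeo(tb, nrow(tbv))
  indexRaster(lstK - 273.15, "LST_C", geotransform = geo$gt, crs = geo$crs,
              date = geo$date)
}
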