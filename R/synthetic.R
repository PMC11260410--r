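## Synthetic multi-date Landsat-like scenes with known ground truth.
##
## Landscape model: a Gaussian-smoothed white-noise field is rank-cut into
## classes at the configured area fractions, which yields contiguous patches
## whose typical diameter scales with `patchScale` while keeping realized
## fractions essentially exact. Scripted land conversion relabels
## edge-biased subsets of a source class between dates.

defaultBandMeans <- function() {
  m <- rbind(
    FC = c(0.03, 0.05, 0.04, 0.45, 0.15, 0.08),
    AG = c(0.05, 0.08, 0.08, 0.35, 0.25, 0.15),
    BS = c(0.15, 0.18, 0.22, 0.26, 0.30, 0.28),
    WB = c(0.06, 0.05, 0.05, 0.02, 0.01, 0.01),
    OT = c(0.25, 0.28, 0.30, 0.40, 0.35, 0.30))
  colnames(m) <- paste0("b", 1:6)
  m
}

#' Configuration for synthetic scene generation
#'
#' Builds a validated [SyntheticConfig-class]. Defaults emulate a dry-zone
#' landscape dominated by forest with agriculture, built-up, water and bare
#' patches, TM-like band spectra whose NDVI ordering is
#' forest > agriculture > other > built-up > water, and a thermal band whose
#' brightness temperature decreases with greenness
#' (TB = tbBaseK + tbNdviSlopeK * NDVI + noise).
#'
#' @param gridRows,gridCols grid size in pixels (>= 16).
#' @param pixelSizeM pixel size in meters.
#' @param seed base RNG seed; every generator output is a pure function of
#'   (config, seed).
#' @param classFractions named fractions over FC, AG, BS, WB, OT summing to 1.
#' @param patchScale mean patch diameter in pixels.
#' @param bandMeans class x band matrix of mean reflectances in [0, 1].
#' @param bandSd common per-band standard deviation used to build diagonal
#'   covariances when `bandCov` is not given.
#' @param bandCov optional list of per-class covariance matrices.
#' @param tbBaseK,tbNdviSlopeK,tbNoiseSdK thermal coupling parameters
#'   (Kelvin; slope is Kelvin per unit NDVI, negative in the default regime).
#' @param transitionRates data.frame(from, to, rate): per date step, the
#'   fraction of the source-class area converted to the target class.
#' @param nodataBorderPx width of the nodata border in pixels.
#' @param spec sensor specification used for DN encoding.
#' @return A [SyntheticConfig-class].
#' @export
#' @examples
#' cfg <- syntheticConfig(gridRows = 64, gridCols = 64, seed = 7)
#' cm <- generateClassMap(cfg)
#' table(mapLabels(cm))
syntheticConfig <- function(gridRows = 128L, gridCols = 128L,
                            pixelSizeM = 30, seed = 1L,
                            classFractions = c(FC = 0.70, AG = 0.15,
                                               BS = 0.05, WB = 0.05,
                                               OT = 0.05),
                            patchScale = 8, bandMeans = defaultBandMeans(),
                            bandSd = 0.02, bandCov = NULL,
                            tbBaseK = 310, tbNdviSlopeK = -10,
                            tbNoiseSdK = 0.2,
                            transitionRates = data.frame(
                              from = c("FC", "FC"), to = c("AG", "BS"),
                              rate = c(0.02, 0.01)),
                            nodataBorderPx = 2L,
                            spec = syntheticSensorSpec()) {
  if (gridRows <= 0 || gridCols <= 0)
    stopf("grid dimensions must be positive")
  if (abs(sum(classFractions) - 1) > 1e-9)
    stopf("class fractions must sum to 1 (got %g)", sum(classFractions))
  if (is.null(bandCov)) {
    bandCov <- lapply(rownames(bandMeans), function(cl)
      diag(bandSd^2, ncol(bandMeans)))
    names(bandCov) <- rownames(bandMeans)
  }
  new("SyntheticConfig",
      gridRows = as.integer(gridRows), gridCols = as.integer(gridCols),
      pixelSizeM = pixelSizeM, seed = as.integer(seed),
      classFractions = classFractions[names(lulcLegend())],
      patchScale = patchScale, bandMeans = bandMeans, bandCov = bandCov,
      tbBaseK = tbBaseK, tbNdviSlopeK = tbNdviSlopeK,
      tbNoiseSdK = tbNoiseSdK, transitionRates = transitionRates,
      nodataBorderPx = as.integer(nodataBorderPx), spec = spec)
}

#' Generate a patchy ground-truth class map
#'
#' Thresholds a Gaussian-smoothed white-noise field by rank at the
#' configured cumulative class fractions, producing contiguous patches with
#' realized fractions exact up to pixel rounding; the configured border is
#' set to nodata (0).
#'
#' @param config a [SyntheticConfig-class].
#' @return A [ClassMap-class] over legend values 1..5 (0 in the border).
#' @export
generateClassMap <- function(config) {
  validObject(config)
  r <- config@gridRows; cc <- config@gridCols
  set.seed(deriveSeed(config@seed, 1L))
  field <- gaussianSmooth(matrix(stats::rnorm(r * cc), r, cc),
                          sigma = config@patchScale / 2)
  n <- r * cc
  rk <- rank(field, ties.method = "first")
  breaks <- round(cumsum(config@classFractions) * n)
  breaks[length(breaks)] <- n
  labels <- matrix(0L, r, cc)
  lo <- 0
  for (i in seq_along(breaks)) {
    if (breaks[i] > lo)
      labels[rk > lo & rk <= breaks[i]] <- i
    lo <- breaks[i]
  }
  b <- config@nodataBorderPx
  if (b > 0) {
    labels[c(seq_len(b), r - seq_len(b) + 1L), ] <- 0L
    labels[, c(seq_len(b), cc - seq_len(b) + 1L)] <- 0L
  }
  classMap(labels,
           geotransform = makeGeotransform(config@pixelSizeM, nrow = r))
}

#' Apply scripted land-cover conversions
#'
#' For each (from, to, rate) rule, relabels approximately rate x area(from)
#' pixels of the source class to the target class. Converted pixels are
#' biased toward patch edges: source pixels are ranked by the smoothed
#' indicator of non-source neighborhood, with a small random jitter, and the
#' top-ranked pixels convert first.
#'
#' @param truth a [ClassMap-class].
#' @param rates data.frame(from, to, rate) with class codes and rates in
#'   [0, 1].
#' @param seed RNG seed.
#' @return A new [ClassMap-class]; unaffected pixels are unchanged.
#' @export
applyChange <- function(truth, rates, seed) {
  if (nrow(rates) && (any(rates$rate < 0) || any(rates$rate > 1)))
    stopf("transition rates must lie in [0, 1]")
  labels <- mapLabels(truth)
  out <- labels
  legend <- mapLegend(truth)
  set.seed(deriveSeed(seed, 2L))
  for (fromCode in unique(rates$from)) {
    fromLab <- legend[[fromCode]]
    rules <- rates[rates$from == fromCode & rates$rate > 0, , drop = FALSE]
    if (!nrow(rules)) next
    src <- which(labels == fromLab)
    if (!length(src)) next
    ks <- round(rules$rate * length(src))
    if (sum(ks) > length(src))
      stopf("transition rates from %s exceed the available area", fromCode)
    ## edge bias: smoothed indicator of "not this class" is highest at the
    ## patch boundary
    other <- matrix(as.numeric(labels != fromLab), nrow(labels), ncol(labels))
    edge <- gaussianSmooth(other, sigma = 2)[src]
    ord <- src[order(-edge, stats::runif(length(src)))]
    used <- 0L
    for (i in seq_len(nrow(rules))) {
      k <- ks[i]
      if (k > 0) {
        out[ord[(used + 1L):(used + k)]] <- legend[[rules$to[i]]]
        used <- used + k
      }
    }
  }
  classMap(out, legend = legend, geotransform = geoTransform(truth),
           crs = crsId(truth), date = gridDate(truth))
}

#' Render a scene from a truth map
#'
#' Reflective bands are drawn per pixel from the class's multivariate
#' Gaussian, clipped to [0, 1] reflectance, and encoded to DN through the
#' sensor spec's inverse gain/offset. The thermal band encodes
#' TB = tbBaseK + tbNdviSlopeK * NDVI + noise (NDVI computed from the drawn
#' reflectances) as radiance via the forward Planck relation with the
#' spec's K1/K2, then to DN, so the downstream calibration chain is
#' genuinely exercised.
#'
#' @param truth a [ClassMap-class].
#' @param config a [SyntheticConfig-class] (shape must match).
#' @param date date label attached to the scene.
#' @return A [RasterScene-class] at stage "dn".
#' @export
renderScene <- function(truth, config, date = "") {
  labels <- mapLabels(truth)
  if (!identical(dim(labels), c(config@gridRows, config@gridCols)))
    stopf("truth map shape does not match the configuration")
  spec <- config@spec
  nref <- ncol(config@bandMeans)
  nb <- nref + 1L
  r <- nrow(labels); cc <- ncol(labels)
  set.seed(deriveSeed(config@seed,
                      3L + sum(utf8ToInt(as.character(date))) %% 500L))
  refl <- array(0, dim = c(r, cc, nref))
  for (cl in rownames(config@bandMeans)) {
    idx <- which(labels == lulcLegend()[[cl]])
    if (!length(idx)) next
    draws <- MASS::mvrnorm(length(idx), mu = config@bandMeans[cl, ],
                           Sigma = config@bandCov[[cl]])
    draws <- pmin(pmax(matrix(draws, nrow = length(idx)), 0), 1)
    for (b in seq_len(nref)) refl[idx + (b - 1L) * r * cc] <- draws[, b]
  }
  nir <- refl[, , spec@bandRoles[["nir"]]]
  red <- refl[, , spec@bandRoles[["red"]]]
  s <- nir + red
  ndviTrue <- ifelse(s > 0, (nir - red) / s, 0)
  tb <- config@tbBaseK + config@tbNdviSlopeK * ndviTrue +
    matrix(stats::rnorm(r * cc, sd = config@tbNoiseSdK), r, cc)
  thermalL <- spec@K1 / (exp(spec@K2 / tb) - 1)

  bands <- array(0, dim = c(r, cc, nb))
  for (b in seq_len(nref))
    bands[, , b] <- (refl[, , b] - spec@offset[b]) / spec@gain[b]
  ti <- spec@bandRoles[["thermal"]]
  bands[, , ti] <- (thermalL - spec@offset[ti]) / spec@gain[ti]
  mask <- labels != 0L
  for (b in seq_len(nb)) bands[, , b][!mask] <- 0
  rasterScene(bands, mask = mask, stage = "dn", spec = spec,
              geotransform = geoTransform(truth), crs = crsId(truth),
              date = date)
}

#' Generate a chained multi-date bundle
#'
#' The first truth map comes from [generateClassMap()]; each subsequent map
#' applies the configured transition rates to its predecessor. One scene is
#' rendered per date. The whole bundle is a pure function of (config, seed).
#'
#' @param config a [SyntheticConfig-class].
#' @param nDates number of dates (>= 2).
#' @param dates optional date labels; defaults to the four-epoch series
#'   1988, 1996, 2009, 2022 extended by 13-year steps if needed.
#' @return A [TruthBundle-class].
#' @export
generateTimeSeries <- function(config, nDates = 4L, dates = NULL) {
  if (nDates < 2) stopf("nDates must be >= 2")
  if (is.null(dates)) {
    base <- c(1988, 1996, 2009, 2022)
    if (nDates > 4)
      base <- c(base, seq(2035, by = 13, length.out = nDates - 4))
    dates <- as.character(base[seq_len(nDates)])
  }
  truths <- vector("list", nDates)
  truths[[1]] <- generateClassMap(config)
  truths[[1]]@date <- dates[1]
  for (t in 2:nDates) {
    truths[[t]] <- applyChange(truths[[t - 1]], config@transitionRates,
                               seed = deriveSeed(config@seed, 10L + t))
    truths[[t]]@date <- dates[t]
  }
  scenes <- lapply(seq_len(nDates), function(t)
    renderScene(truths[[t]], config, date = dates[t]))
  new("TruthBundle", scenes = scenes, truthMaps = truths, config = config)
}

#' Sample labeled reference points from a truth map
#'
#' Draws `n` points uniformly without replacement over valid pixels and
#' labels them with the truth class; a fraction `labelNoise` of points is
#' relabeled uniformly to one of the other legend classes, emulating
#' imperfect reference interpretation.
#'
#' @param truth a [ClassMap-class].
#' @param n number of points.
#' @param labelNoise fraction in [0, 1) of points given a wrong label.
#' @param seed RNG seed.
#' @return data.frame(row, col, refLabel).
#' @export
referencePoints <- function(truth, n, labelNoise = 0, seed = 1L) {
  if (labelNoise < 0 || labelNoise >= 1)
    stopf("labelNoise must lie in [0, 1)")
  labels <- mapLabels(truth)
  valid <- which(labels != 0L)
  if (n > length(valid)) stopf("n exceeds the number of valid pixels")
  present <- length(unique(labels[valid]))
  if (n < present) stopf("n must be at least the number of present classes")
  set.seed(deriveSeed(seed, 4L))
  pick <- sample(valid, n)
  ref <- labels[pick]
  m <- round(labelNoise * n)
  if (m > 0) {
    flip <- sample(seq_len(n), m)
    codes <- unname(mapLegend(truth))
    ref[flip] <- vapply(ref[flip], function(l)
      sample(setdiff(codes, l), 1L), integer(1))
  }
  rc <- arrayInd(pick, dim(labels))
  data.frame(row = rc[, 1], col = rc[, 2], refLabel = as.integer(ref))
}
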