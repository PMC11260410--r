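## End-to-end orchestration on a synthetic multi-date bundle:
## simulate -> calibrate -> DOS -> classify -> filter -> assess ->
## cross-tabulate -> index chain -> statistics and regressions.

sampleTraining <- function(truth, scene, perClass, seed, bands) {
  labels <- mapLabels(truth)
  set.seed(deriveSeed(seed, 7L))
  rows <- list()
  for (cl in names(mapLegend(truth))) {
    idx <- which(labels == mapLegend(truth)[[cl]])
    if (!length(idx)) next
    pick <- sample(idx, min(perClass, length(idx)))
    feats <- vapply(bands, function(b) scene@bands[, , b][pick],
                    numeric(length(pick)))
    rows[[cl]] <- data.frame(class = cl, matrix(feats, nrow = length(pick)))
  }
  out <- do.call(rbind, rows)
  names(out) <- c("class", paste0("b", bands))
  rownames(out) <- NULL
  out
}

#' Run the full forest-monitoring pipeline on a synthetic bundle
#'
#' Generates a multi-date bundle, calibrates each scene (DN to radiance,
#' dark-object subtraction), trains a maximum-likelihood classifier per
#' date from truth-labelled pixels, classifies and majority-filters,
#' assesses accuracy on stratified points referenced against the truth
#' map, cross-tabulates consecutive date pairs plus the endpoints,
#' computes NDVI, PV, emissivity, brightness temperature, LST, VCI and
#' ECI, and fits the LST~NDVI, ECI~LST and ECI~NDVI regressions per date.
#' With `outDir` set, writes class maps and index rasters (.asc), CSV
#' tables and a JSON run manifest with content hashes.
#'
#' @param config a [SyntheticConfig-class]; its seed drives all stages.
#' @param nDates number of dates (default 4).
#' @param outDir optional output directory.
#' @param trainPerClass training pixels sampled per class and date.
#' @param assessPoints stratified reference points per date.
#' @param regressSampleN pixel sample for the regressions.
#' @return Invisibly, a list with the bundle, classified maps, accuracy
#'   reports, change matrices, area/gain-loss tables, index rasters,
#'   statistics, regressions and the manifest.
#' @export
runPipeline <- function(config = syntheticConfig(), nDates = 4L,
                        outDir = NULL, trainPerClass = 100L,
                        assessPoints = 600L, regressSampleN = 5000L) {
  seed <- config@seed
  bundle <- generateTimeSeries(config, nDates)
  dates <- vapply(bundleScenes(bundle), gridDate, "")
  roles <- config@spec@bandRoles
  reflBands <- setdiff(seq_along(config@spec@gain), roles[["thermal"]])

  classified <- list(); reports <- list(); areas <- list()
  ndviR <- list(); lstR <- list(); eciR <- list()
  statsTab <- list(); regress <- list()

  for (t in seq_len(nDates)) {
    truth <- bundleTruth(bundle)[[t]]
    scene <- dosCorrection(dnToRadiance(bundleScenes(bundle)[[t]]))

    training <- sampleTraining(truth, scene, trainPerClass,
                               seed + t, reflBands)
    model <- fitClassModels(training)
    cmap <- majorityFilter(classifyScene(scene, model))
    classified[[t]] <- cmap

    pts <- stratifiedSample(cmap, assessPoints, seed = seed + t)
    pts$refLabel <- mapLabels(truth)[cbind(pts$row, pts$col)]
    pts <- pts[pts$refLabel > 0L, , drop = FALSE]
    reports[[t]] <- assessAccuracy(cmap, pts)
    areas[[t]] <- areaSummary(cmap)

    nd <- sceneNdvi(scene)
    pv <- proportionVegetation(nd)
    eps <- emissivity(pv)
    tb <- sceneBrightnessTemperature(scene)
    lst <- landSurfaceTemperature(tb, eps, config@spec@lambdaUm)
    ndviR[[t]] <- nd; lstR[[t]] <- lst
    eciR[[t]] <- eci(lst, nd)

    regress[[t]] <- list(
      lst_ndvi = regressIndices(lst, nd, regressSampleN, seed = seed + t),
      eci_lst = regressIndices(eciR[[t]], lst, regressSampleN,
                               seed = seed + t),
      eci_ndvi = regressIndices(eciR[[t]], nd, regressSampleN,
                                seed = seed + t))
    statsTab[[t]] <- list(ndvi = rasterStats(nd), lst = rasterStats(lst),
                          eci = rasterStats(eciR[[t]]))
  }
  vciR <- vci(ndviR)

  pairs <- cbind(seq_len(nDates - 1L), 2:nDates)
  if (nDates > 2) pairs <- rbind(pairs, c(1L, nDates))
  changes <- lapply(seq_len(nrow(pairs)), function(i)
    crosstab(classified[[pairs[i, 1]]], classified[[pairs[i, 2]]]))

  manifest <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    wAsc <- function(vals, gt, name) {
      p <- file.path(outDir, name)
      writeAsciiGrid(vals, gt, p)
      files <<- c(files, p)
    }
    wCsv <- function(df, name) {
      p <- file.path(outDir, name)
      writeTable(df, p)
      files <<- c(files, p)
    }
    for (t in seq_len(nDates)) {
      d <- dates[t]
      cmt <- classified[[t]]
      lab <- mapLabels(cmt); lab[lab == 0L] <- NA
      wAsc(lab, geoTransform(cmt), sprintf("classmap_%s.asc", d))
      wAsc(indexValues(ndviR[[t]]), geoTransform(ndviR[[t]]),
           sprintf("ndvi_%s.asc", d))
      wAsc(indexValues(lstR[[t]]), geoTransform(lstR[[t]]),
           sprintf("lst_%s.asc", d))
      wAsc(indexValues(vciR[[t]]), geoTransform(vciR[[t]]),
           sprintf("vci_%s.asc", d))
      wAsc(indexValues(eciR[[t]]), geoTransform(eciR[[t]]),
           sprintf("eci_%s.asc", d))
    }
    areaTab <- do.call(rbind, lapply(seq_len(nDates), function(t)
      cbind(date = dates[t], areas[[t]])))
    wCsv(areaTab, "area_summary.csv")
    changeTab <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      gl <- gainLossNet(changes[[i]])
      cbind(period = paste(dates[pairs[i, 1]], dates[pairs[i, 2]],
                           sep = "-"), gl)
    }))
    wCsv(changeTab, "gain_loss_net.csv")
    accTab <- do.call(rbind, lapply(seq_len(nDates), function(t) {
      rp <- reports[[t]]
      data.frame(date = dates[t], overallAccuracy = rp@overallAccuracy,
                 kappa = rp@kappa, nPoints = rp@nPoints,
                 passesThreshold = rp@passesThreshold)
    }))
    wCsv(accTab, "accuracy.csv")
    regTab <- do.call(rbind, lapply(seq_len(nDates), function(t)
      do.call(rbind, lapply(names(regress[[t]]), function(nm) {
        rr <- regress[[t]][[nm]]
        data.frame(date = dates[t], pair = nm, slope = rr@slope,
                   intercept = rr@intercept, rSquared = rr@rSquared,
                   n = rr@nPoints)
      }))))
    wCsv(regTab, "regressions.csv")
    statTab <- do.call(rbind, lapply(seq_len(nDates), function(t)
      do.call(rbind, lapply(names(statsTab[[t]]), function(nm) {
        s <- statsTab[[t]][[nm]]
        data.frame(date = dates[t], index = nm, min = s@min, max = s@max,
                   mean = s@mean, sd = s@sd, n = s@nValid)
      }))))
    wCsv(statTab, "index_stats.csv")
    manifest <- list(
      seed = seed, nDates = nDates, dates = dates,
      gridRows = config@gridRows, gridCols = config@gridCols,
      pixelSizeM = config@pixelSizeM, trainPerClass = trainPerClass,
      assessPoints = assessPoints, regressSampleN = regressSampleN,
      rVersion = as.character(getRversion()),
      files = lapply(files, function(p)
        list(path = basename(p), md5 = unname(tools::md5sum(p)))))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(bundle = bundle, classified = classified,
                 reports = reports, changes = changes, areas = areas,
                 ndvi = ndviR, lst = lstR, vci = vciR, eci = eciR,
                 regressions = regress, stats = statsTab,
                 manifest = manifest, dates = dates))
}
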