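test_that("class-map generation hits the requested fractions and is deterministic", {
  cfg <- syntheticConfig(gridRows = 128, gridCols = 128, seed = 3,
                         classFractions = c(FC = 0.7, AG = 0.15, BS = 0.05,
                                            WB = 0.05, OT = 0.05),
                         patchScale = 8)
  cm1 <- generateClassMap(cfg)
  cm2 <- generateClassMap(cfg)
  expect_identical(mapLabels(cm1), mapLabels(cm2))

  lab <- mapLabels(cm1)
  valid <- lab[lab > 0]
  forestFrac <- mean(valid == 1L)
  expect_gte(forestFrac, 0.65)
  expect_lte(forestFrac, 0.75)
  # every class realised within +-0.05 of its request
  for (i in 1:5)
    expect_lt(abs(mean(valid == i) - cfg@classFractions[i]), 0.05)
  # border is nodata
  expect_true(all(lab[1:2, ] == 0L))
})

test_that("a single-class configuration labels every valid pixel that class", {
  cfg <- smallConfig(classFractions = c(FC = 1, AG = 0, BS = 0, WB = 0,
                                        OT = 0))
  lab <- mapLabels(generateClassMap(cfg))
  expect_true(all(lab[lab > 0] == 1L))
})

test_that("invalid configurations are rejected", {
  expect_error(syntheticConfig(gridRows = -4), "positive")
  expect_error(syntheticConfig(classFractions = c(FC = 0.9, AG = 0.2,
                                                  BS = 0, WB = 0, OT = 0)),
               "sum to 1")
  expect_error(syntheticConfig(gridRows = 8, gridCols = 8), ">= 16")
})

test_that("applyChange converts the scripted number of pixels, edge-biased", {
  cfg <- syntheticConfig(gridRows = 128, gridCols = 128, seed = 9)
  truth <- generateClassMap(cfg)
  nForest <- sum(mapLabels(truth) == 1L)

  none <- applyChange(truth, data.frame(from = "FC", to = "AG", rate = 0),
                      seed = 1)
  expect_identical(mapLabels(none), mapLabels(truth))

  all <- applyChange(truth, data.frame(from = "FC", to = "AG", rate = 1),
                     seed = 1)
  expect_equal(sum(mapLabels(all) == 1L), 0)

  some <- applyChange(truth, data.frame(from = "FC", to = "AG",
                                        rate = 0.05), seed = 1)
  converted <- sum(mapLabels(truth) == 1L & mapLabels(some) == 2L)
  expect_lt(abs(converted - 0.05 * nForest), 0.01 * 0.05 * nForest + 1)
  # untouched pixels keep their label
  expect_true(all(mapLabels(some)[mapLabels(truth) != 1L] ==
                    mapLabels(truth)[mapLabels(truth) != 1L]))
  expect_error(applyChange(truth, data.frame(from = "FC", to = "AG",
                                             rate = 1.2), seed = 1),
               "\\[0, 1\\]")
})

test_that("noiseless rendering gives each class exactly its mean spectrum", {
  cfg <- smallConfig(bandSd = 0, tbNoiseSdK = 0)
  truth <- generateClassMap(cfg)
  scene <- dnToRadiance(renderScene(truth, cfg, "1988"))
  lab <- mapLabels(truth)
  for (cl in c("FC", "WB")) {
    idx <- which(lab == lulcLegend()[[cl]])
    for (b in 1:6) {
      vals <- sceneBands(scene)[, , b][idx]
      expect_equal(vals, rep(cfg@bandMeans[cl, b], length(idx)),
                   tolerance = 1e-9)
    }
  }
})

test_that("the rendered thermal band encodes the configured NDVI coupling", {
  cfg <- syntheticConfig(gridRows = 96, gridCols = 96, seed = 5,
                         tbNdviSlopeK = -10, tbNoiseSdK = 0.2)
  truth <- generateClassMap(cfg)
  scene <- dnToRadiance(renderScene(truth, cfg, "1988"))
  roles <- cfg@spec@bandRoles
  mask <- sceneMask(scene)
  nir <- sceneBands(scene)[, , roles[["nir"]]][mask]
  red <- sceneBands(scene)[, , roles[["red"]]][mask]
  ndviTrue <- (nir - red) / (nir + red)
  tb <- indexValues(sceneBrightnessTemperature(scene))[mask]
  fit <- lm(tb ~ ndviTrue)
  expect_lt(abs(coef(fit)[2] - (-10)), 0.5)

  # decoupled limit: zero slope leaves the thermal band class-independent
  cfg0 <- syntheticConfig(gridRows = 96, gridCols = 96, seed = 5,
                          tbNdviSlopeK = 0, tbNoiseSdK = 0.2)
  sc0 <- dnToRadiance(renderScene(generateClassMap(cfg0), cfg0, "1988"))
  tb0 <- indexValues(sceneBrightnessTemperature(sc0))[sceneMask(sc0)]
  nir0 <- sceneBands(sc0)[, , roles[["nir"]]][sceneMask(sc0)]
  red0 <- sceneBands(sc0)[, , roles[["red"]]][sceneMask(sc0)]
  fit0 <- lm(tb0 ~ I((nir0 - red0) / (nir0 + red0)))
  expect_lt(abs(coef(fit0)[2]), 0.1)
})

test_that("time series are deterministic, conservative and monotone under loss", {
  cfg <- smallConfig()
  b1 <- generateTimeSeries(cfg, 4)
  b2 <- generateTimeSeries(cfg, 4)
  expect_identical(lapply(bundleTruth(b1), mapLabels),
                   lapply(bundleTruth(b2), mapLabels))
  expect_identical(lapply(bundleScenes(b1), sceneBands),
                   lapply(bundleScenes(b2), sceneBands))

  validCounts <- vapply(bundleTruth(b1),
                        function(m) sum(mapLabels(m) > 0), 0L)
  expect_true(all(validCounts == validCounts[1]))

  forest <- vapply(bundleTruth(b1), function(m) sum(mapLabels(m) == 1L), 0L)
  expect_true(all(diff(forest) <= 0))

  static <- generateTimeSeries(
    smallConfig(transitionRates = data.frame(from = character(),
                                             to = character(),
                                             rate = numeric())), 4)
  labs <- lapply(bundleTruth(static), mapLabels)
  expect_identical(labs[[1]], labs[[4]])

  expect_error(generateTimeSeries(cfg, 1), ">= 2")
})

test_that("reference points carry truth labels with the scripted noise", {
  truth <- bundleTruth(fixtureBundle())[[1]]
  pts0 <- referencePoints(truth, 200, labelNoise = 0, seed = 3)
  expect_equal(pts0$refLabel,
               mapLabels(truth)[cbind(pts0$row, pts0$col)])

  pts <- referencePoints(truth, 600, labelNoise = 0.1, seed = 3)
  discord <- sum(pts$refLabel !=
                   mapLabels(truth)[cbind(pts$row, pts$col)])
  expect_equal(discord, 60)
  expect_true(all(mapLabels(truth)[cbind(pts$row, pts$col)] > 0))

  expect_error(referencePoints(truth, 1e6, seed = 1), "exceeds")
})
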