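test_that("NDVI arithmetic, undefined pixels and antisymmetry", {
  nir <- matrix(c(0.6, 0.3, 0.0, 0.5), 2)
  red <- matrix(c(0.2, 0.3, 0.0, 0.1), 2)
  nd <- ndvi(nir, red)
  v <- indexValues(nd)
  expect_equal(v[1, 1], 0.5)
  expect_equal(v[2, 1], 0)
  expect_true(is.na(v[1, 2])) # NIR + RED = 0
  expect_equal(indexKind(nd), "NDVI")

  # swapping NIR and RED negates NDVI
  sw <- indexValues(ndvi(red, nir))
  expect_equal(sw[!is.na(sw)], -v[!is.na(v)])

  expect_error(ndvi(nir, matrix(0, 3, 3)), "shapes differ")
})

test_that("NDVI density classes follow the documented thresholds", {
  v <- matrix(c(-0.1, 0.0, 0.1, 0.2, 0.35, 0.5, 0.51, 0.75), 2)
  cm <- classifyNdvi(indexRaster(v, "NDVI"))
  lab <- mapLabels(cm)
  expect_equal(as.vector(lab), c(1L, 2L, 2L, 3L, 3L, 3L, 4L, 4L))
  expect_error(classifyNdvi(indexRaster(v, "ECI")), "kind")
})

test_that("proportion of vegetation is the squared min-max normalization", {
  v <- matrix(c(0.0, 0.4, 0.8, 0.2), 2)
  pv <- indexValues(proportionVegetation(indexRaster(v, "NDVI")))
  expect_equal(pv[1, 1], 0)   # at scene minimum
  expect_equal(pv[2, 2], 0.0625)
  expect_equal(pv[1, 2], 1)   # at scene maximum
  expect_equal(pv[2, 1], 0.25) # midpoint -> (0.5)^2

  expect_error(proportionVegetation(indexRaster(matrix(0.3, 4, 4), "NDVI")),
               "degenerate")

  # PV invariant under shared affine rescaling of NDVI
  v2 <- 0.5 * v + 0.1
  expect_equal(pv, indexValues(proportionVegetation(indexRaster(v2, "NDVI"))))
})

test_that("emissivity endpoints match the linear mixing coefficients", {
  pv <- indexRaster(matrix(c(0, 0.5, 1, 0.25), 2), "PV")
  e <- indexValues(emissivity(pv))
  expect_equal(e[1, 1], 0.986)
  expect_equal(e[2, 1], 0.988)
  expect_equal(e[1, 2], 0.990)
})

test_that("brightness temperature inverts the Planck relation", {
  K1 <- 607.76; K2 <- 1260.56
  L <- matrix(c(K1 / (exp(1) - 1), K1 / (exp(2) - 1), -1, 9.5), 2)
  tb <- indexValues(brightnessTemperature(L, K1, K2))
  expect_equal(tb[1, 1], K2)
  expect_equal(tb[2, 1], K2 / 2)
  expect_true(is.na(tb[1, 2])) # nonpositive radiance

  # round trip radiance -> TB -> radiance
  Lr <- matrix(runif(100, 5, 12), 10)
  tbr <- indexValues(brightnessTemperature(Lr, K1, K2))
  back <- K1 / (exp(K2 / tbr) - 1)
  expect_equal(back, Lr, tolerance = 1e-9)
})

test_that("single-channel LST matches hand evaluation and the blackbody limit", {
  tb <- indexRaster(matrix(300, 2, 2), "TB_K")
  eps1 <- indexRaster(matrix(1, 2, 2), "EMISSIVITY")
  lst1 <- indexValues(landSurfaceTemperature(tb, eps1, 10.8))
  expect_equal(lst1, matrix(300 - 273.15, 2, 2)) # ln 1 = 0

  epsB <- indexRaster(matrix(1 - 1e-12, 2, 2), "EMISSIVITY")
  lstB <- indexValues(landSurfaceTemperature(tb, epsB, 10.8))
  expect_lt(max(abs(lstB + 273.15 - 300)), 1e-6)

  eps <- indexRaster(matrix(0.986, 2, 2), "EMISSIVITY")
  lst <- indexValues(landSurfaceTemperature(tb, eps, 10.8))
  byHand <- 300 / (1 + (10.8e-6 * 300 / 1.438e-2) * log(0.986)) - 273.15
  expect_equal(lst[1, 1], byHand)
  expect_equal(lst[1, 1], 27.8059, tolerance = 1e-4)

  # LST strictly decreases as emissivity rises toward 1 (fixed TB > 0)
  epsGrid <- seq(0.95, 1, by = 0.005)
  lstSweep <- vapply(epsGrid, function(e)
    indexValues(landSurfaceTemperature(
      indexRaster(matrix(300, 1, 1), "TB_K"),
      indexRaster(matrix(e, 1, 1), "EMISSIVITY"), 10.8))[1, 1], 0)
  expect_true(all(diff(lstSweep) < 0))
})

test_that("VCI normalizes per pixel across the stack with the right endpoints", {
  stackVals <- c(0.2, 0.4, 0.6, 0.3)
  layers <- lapply(stackVals, function(v)
    indexRaster(matrix(v, 3, 3), "NDVI"))
  # add a second pixel trajectory so the stack is not constant per layer
  for (i in seq_along(layers)) layers[[i]]@values[2, 2] <- stackVals[5 - i]
  out <- vci(layers)
  got <- vapply(out, function(r) indexValues(r)[1, 1], 0)
  expect_equal(got, c(0, 50, 100, 25))

  expect_error(vci(layers[1]), "at least 2")

  # invariance under shared affine rescaling of the NDVI stack
  resc <- lapply(layers, function(l)
    indexRaster(0.4 * indexValues(l) + 0.05, "NDVI"))
  out2 <- vci(resc)
  for (t in seq_along(out))
    expect_equal(indexValues(out[[t]]), indexValues(out2[[t]]))

  # degenerate per-pixel range -> nodata
  flat <- lapply(1:3, function(i) indexRaster(matrix(0.5, 2, 2), "NDVI"))
  expect_true(all(is.na(indexValues(vci(flat)[[1]]))))
})

test_that("VCI drought classes bin at 50/30/20/10", {
  v <- matrix(c(75, 50, 49, 30, 25, 20, 15, 10, 5), 3)
  cm <- classifyVci(indexRaster(v, "VCI"))
  expect_equal(as.vector(mapLabels(cm)),
               c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L))
})

test_that("histogram equalization is rank-based with average ties", {
  s <- indexValues(histogramStretch(matrix(c(10, 20, 30), 1)))
  expect_equal(as.vector(s), c(1, 128, 255))

  # monotone non-decreasing in the input; integer-valued in 1..255
  set.seed(21)
  x <- matrix(rnorm(500), 20)
  sx <- indexValues(histogramStretch(x))
  o <- order(x)
  expect_true(all(diff(sx[o]) >= 0))
  expect_true(all(sx >= 1 & sx <= 255))
  expect_true(all(sx == round(sx)))

  # constant input maps to the midpoint
  expect_true(all(indexValues(histogramStretch(matrix(7, 4, 4))) == 128))

  # ties share an average rank
  st <- indexValues(histogramStretch(matrix(c(1, 2, 2, 3), 1)))
  expect_equal(as.vector(st), c(1, round(1 + 254 * 1.5 / 3),
                                round(1 + 254 * 1.5 / 3), 255))

  # idempotence on ranks: restretching preserves order and endpoints
  s2 <- indexValues(histogramStretch(indexRaster(sx, "STRETCHED")))
  expect_equal(rank(s2), rank(sx))
  expect_equal(range(s2), c(1, 255))
})

test_that("ECI rises with thermal rank and falls with greenness rank", {
  set.seed(9)
  lst <- indexRaster(matrix(runif(100, 20, 40), 10), "LST_C")
  flatN <- indexRaster(matrix(0.4, 10, 10), "NDVI")
  e1 <- indexValues(eci(lst, flatN))
  o <- order(indexValues(lst))
  expect_true(all(diff(e1[o]) > 0)) # strictly increasing in LST rank

  ndv <- indexRaster(matrix(runif(100, -0.2, 0.8), 10), "NDVI")
  flatL <- indexRaster(matrix(25, 10, 10), "LST_C")
  e2 <- indexValues(eci(flatL, ndv))
  o2 <- order(indexValues(ndv))
  expect_true(all(diff(e2[o2]) < 0)) # strictly decreasing in NDVI rank

  # extremes of the ratio
  both <- eci(lst, ndv)
  expect_true(all(indexValues(both) >= 1 / 255 - 1e-12))
  expect_true(all(indexValues(both) <= 255 + 1e-12))

  # equal stretched values give exactly 1
  e3 <- indexValues(eci(indexRaster(matrix(25, 3, 3), "LST_C"),
                        indexRaster(matrix(0.4, 3, 3), "NDVI")))
  expect_true(all(e3 == 1))

  # non-vegetation masking drops NDVI < 0 pixels
  masked <- eci(lst, ndv, maskNonveg = TRUE)
  expect_true(all(is.na(indexValues(masked)[indexValues(ndv) < 0])))
})

test_that("ECI criticality classes: terciles, fixed breaks and degenerate input", {
  set.seed(14)
  v <- matrix(runif(10000), 100)
  cm <- classifyEci(indexRaster(v, "ECI"))
  shares <- table(mapLabels(cm)) / 10000
  expect_true(all(abs(shares - 1 / 3) < 0.02))

  fixed <- classifyEci(indexRaster(matrix(c(1, 3, 6, 2), 2), "ECI"),
                       breaks = c(2, 5))
  expect_equal(as.vector(mapLabels(fixed)), c(1L, 2L, 3L, 1L))

  flat <- classifyEci(indexRaster(matrix(2.5, 4, 4), "ECI"))
  expect_true(all(mapLabels(flat) == 2L))
})

test_that("the second radiation constant matches its analytic value", {
  # h*c/k_B with CODATA constants is 1.43878e-2 m K
  rhoCodata <- thermalRho(6.62607015e-34, 2.99792458e8, 1.380649e-23)
  expect_equal(rhoCodata, 1.4388e-2, tolerance = 1e-4)
  # the rounded-constant evaluation agrees at 3 significant figures
  expect_equal(signif(thermalRho(), 3), signif(rhoCodata, 3))
  # the LST default (1.438e-2) sits within 0.2% of the analytic value
  expect_lt(abs(1.438e-2 - rhoCodata) / rhoCodata, 0.002)
})
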