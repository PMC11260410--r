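test_that("model fitting reproduces hand-computed moments and errors", {
  tr <- data.frame(class = "A",
                   b1 = c(0, 2, 0, 2), b2 = c(0, 0, 2, 2))
  tr <- rbind(tr, data.frame(class = "B", b1 = 10 + rnorm(8, sd = 0.1),
                             b2 = rnorm(8, sd = 0.1)))
  model <- fitClassModels(tr)
  expect_equal(model@means$A, c(b1 = 1, b2 = 1))
  expect_equal(unname(model@covs$A), diag(4 / 3, 2))
  expect_equal(unname(model@priors), c(0.5, 0.5))

  tiny <- data.frame(class = "A", b1 = c(0, 1), b2 = c(0, 1))
  expect_error(fitClassModels(tiny), "class A")

  degen <- data.frame(class = "A", b1 = c(1, 1, 1, 1), b2 = c(0, 1, 2, 3))
  expect_warning(m2 <- fitClassModels(degen), "ridge")
  expect_true(all(eigen(m2@covs$A)$values > 0))
})

test_that("fitted moments recover a known Gaussian within 3 standard errors", {
  set.seed(31)
  n <- 5000
  mu <- c(0.1, 0.4, 0.25)
  Sigma <- diag(c(0.02, 0.03, 0.01)^2)
  x <- MASS::mvrnorm(n, mu, Sigma)
  df <- data.frame(class = "FC", x)
  model <- fitClassModels(df)
  se <- sqrt(diag(Sigma) / n)
  expect_true(all(abs(model@means$FC - mu) < 3 * se))
})

test_that("the weighted distance matches the Gaussian log-density oracle", {
  tr <- data.frame(class = "A", b1 = c(0, 2, 0, 2), b2 = c(0, 0, 2, 2))
  model <- fitClassModels(tr, priors = c(A = 1))
  model@covs$A <- diag(2)
  expect_equal(mlcDiscriminant(model@means$A, model, "A"), 0)
  expect_equal(mlcDiscriminant(model@means$A + c(1, 0), model, "A"), -0.5)
  expect_error(mlcDiscriminant(c(1, 2, 3), model, "A"), "length")

  # random 3-band cases against the closed-form log-pdf
  set.seed(17)
  for (rep in 1:20) {
    A <- matrix(rnorm(9), 3)
    Sigma <- crossprod(A) + diag(0.5, 3)
    mu <- rnorm(3)
    prior <- 0.37
    m <- new("GaussianClassModel", means = list(c = mu, d = mu + 10),
             covs = list(c = Sigma, d = Sigma),
             priors = c(c = prior, d = 1 - prior), bandCount = 3L)
    x <- rnorm(3)
    expect_equal(mlcDiscriminant(x, m, "c"),
                 log(prior) + gaussianLogDensity(x, mu, Sigma) +
                   1.5 * log(2 * pi),
                 tolerance = 1e-10)
  }
})

test_that("classification argmax agrees with a brute-force Bayes oracle", {
  set.seed(23)
  p <- 3; k <- 4
  mus <- lapply(1:k, function(i) rnorm(p, mean = i))
  Sigmas <- lapply(1:k, function(i) {
    A <- matrix(rnorm(p * p, sd = 0.4), p); crossprod(A) + diag(0.3, p)
  })
  priors <- c(0.4, 0.3, 0.2, 0.1)
  model <- new("GaussianClassModel",
               means = setNames(mus, paste0("k", 1:k)),
               covs = setNames(Sigmas, paste0("k", 1:k)),
               priors = setNames(priors, paste0("k", 1:k)),
               bandCount = as.integer(p))
  n <- 1200
  X <- matrix(rnorm(n * p, mean = 2.5, sd = 2), n)
  dPkg <- sapply(paste0("k", 1:k), function(cl)
    apply(X, 1, mlcDiscriminant, model = model, class = cl))
  dOracle <- sapply(1:k, function(i)
    log(priors[i]) + apply(X, 1, gaussianLogDensity, mu = mus[[i]],
                           sigma = Sigmas[[i]]))
  expect_equal(apply(dPkg, 1, which.max), apply(dOracle, 1, which.max))
})

test_that("equal priors and shared spherical covariance reduce MLC to nearest mean", {
  set.seed(41)
  p <- 4; k <- 5
  mus <- lapply(1:k, function(i) runif(p, 0, 1))
  model <- new("GaussianClassModel",
               means = setNames(mus, names(lulcLegend())),
               covs = setNames(replicate(k, diag(0.05^2, p),
                                         simplify = FALSE),
                               names(lulcLegend())),
               priors = setNames(rep(1 / k, k), names(lulcLegend())),
               bandCount = as.integer(p))
  X <- matrix(runif(300 * p), 300)
  dPkg <- sapply(names(lulcLegend()), function(cl)
    apply(X, 1, mlcDiscriminant, model = model, class = cl))
  dist2 <- sapply(mus, function(m) colSums((t(X) - m)^2))
  expect_equal(apply(dPkg, 1, which.max), apply(dist2, 1, which.min))
})

test_that("labels are invariant to a common positive rescaling", {
  cfg <- smallConfig()
  bundle <- fixtureBundle()
  scene <- fixtureCalibrated()
  truth <- bundleTruth(bundle)[[1]]
  set.seed(8)
  idx <- lapply(1:5, function(l) sample(which(mapLabels(truth) == l), 30))
  feats <- do.call(rbind, lapply(1:5, function(l)
    sapply(1:6, function(b) sceneBands(scene)[, , b][idx[[l]]])))
  tr <- data.frame(class = rep(names(lulcLegend()), each = 30), feats)
  model <- fitClassModels(tr)
  map1 <- classifyScene(scene, model)

  s <- 7.5
  scene2 <- scene
  scene2@bands <- scene@bands * s
  model2 <- model
  model2@means <- lapply(model@means, `*`, s)
  model2@covs <- lapply(model@covs, `*`, s^2)
  map2 <- classifyScene(scene2, model2)
  expect_identical(mapLabels(map1), mapLabels(map2))

  # well-separated recovery on the synthetic scene
  agree <- mean(mapLabels(map1)[sceneMask(scene)] ==
                  mapLabels(truth)[sceneMask(scene)])
  expect_gte(agree, 0.95)

  # nodata-only scene classifies to all-zero
  empty <- scene
  empty@mask[] <- FALSE
  expect_true(all(mapLabels(classifyScene(empty, model)) == 0L))
})

test_that("majority filtering removes salt-and-pepper and is label-conservative", {
  base <- matrix(1L, 11, 11)
  base[6, 6] <- 2L
  m <- classMap(base)
  f <- majorityFilter(m)
  expect_true(all(mapLabels(f) == 1L))

  uniform <- classMap(matrix(3L, 8, 8))
  expect_identical(mapLabels(majorityFilter(uniform)),
                   mapLabels(uniform))

  expect_error(majorityFilter(m, window = 4), "odd")

  set.seed(12)
  rnd <- classMap(matrix(sample(1:5, 64 * 64, TRUE), 64))
  f1 <- majorityFilter(rnd)
  f2 <- majorityFilter(f1)
  changed1 <- sum(mapLabels(f1) != mapLabels(rnd))
  changed2 <- sum(mapLabels(f2) != mapLabels(f1))
  expect_lte(changed2, changed1)

  # never introduces a label absent from the 3x3 window
  lab0 <- mapLabels(rnd); lab1 <- mapLabels(f1)
  idx <- cbind(sample(2:63, 200, TRUE), sample(2:63, 200, TRUE))
  for (i in seq_len(nrow(idx))) {
    r <- idx[i, 1]; cc <- idx[i, 2]
    expect_true(lab1[r, cc] %in% lab0[(r - 1):(r + 1), (cc - 1):(cc + 1)])
  }
})
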