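# Shared fixtures, generated in code and cached per test run.

.fixtures <- new.env(parent = emptyenv())

smallConfig <- function(seed = 7L, ...) {
  syntheticConfig(gridRows = 64L, gridCols = 64L, seed = seed, ...)
}

fixtureBundle <- function() {
  if (is.null(.fixtures$bundle))
    .fixtures$bundle <- generateTimeSeries(smallConfig(), nDates = 4L)
  .fixtures$bundle
}

# A calibrated (radiance, DOS-corrected) copy of the first bundle scene.
fixtureCalibrated <- function() {
  if (is.null(.fixtures$cal))
    .fixtures$cal <- dosCorrection(dnToRadiance(bundleScenes(
      fixtureBundle())[[1]]))
  .fixtures$cal
}

# Independent log-density oracle for the Gaussian discriminant, built from
# base determinant() and mahalanobis() rather than the package's Cholesky
# path.
gaussianLogDensity <- function(x, mu, sigma) {
  k <- length(mu)
  -0.5 * (k * log(2 * pi) + as.numeric(determinant(sigma)$modulus) +
            mahalanobis(matrix(x, 1), mu, sigma))
}

randomConfusion <- function(k, n = 200L) {
  counts <- matrix(rmultinom(1, n, prob = runif(k * k))[, 1], k, k)
  confusionMatrix(counts, classLabels = paste0("c", seq_len(k)))
}
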