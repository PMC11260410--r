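## Gaussian maximum-likelihood classification.
##
## Each class c is modelled by a multivariate Gaussian (M_c, Cov_c) with
## prior a_c; a pixel vector X is scored by the weighted distance
##   D = ln(a_c) - 0.5 ln|Cov_c| - 0.5 (X - M_c)' Cov_c^-1 (X - M_c)
## and labelled argmax_c D. Up to the class-independent -k/2 ln(2*pi), D is
## the log of the prior-weighted Gaussian density, so the argmax is the
## Bayes rule under the model.

#' Fit per-class Gaussian models from training samples
#'
#' Means are sample means; covariances use the n-1 denominator. A
#' near-singular covariance is ridge-regularized (delta = 1e-6 times the
#' mean diagonal) with a warning; fitting fails only if it stays singular.
#'
#' @param training data.frame whose first column is the class label and
#'   remaining columns the band values, or a list with elements `labels`
#'   and `features`.
#' @param priors optional named prior probabilities (must sum to 1);
#'   default equal across classes.
#' @return A [GaussianClassModel-class].
#' @export
fitClassModels <- function(training, priors = NULL) {
  if (is.data.frame(training)) {
    labels <- as.character(training[[1]])
    feats <- as.matrix(training[, -1, drop = FALSE])
  } else {
    labels <- as.character(training$labels)
    feats <- as.matrix(training$features)
  }
  p <- ncol(feats)
  classes <- sort(unique(labels))
  means <- list(); covs <- list()
  for (cl in classes) {
    x <- feats[labels == cl, , drop = FALSE]
    if (nrow(x) < p + 1L)
      stopf("class %s has %d samples; at least %d (bands + 1) are required",
            cl, nrow(x), p + 1L)
    mu <- colMeans(x)
    cv <- stats::cov(x)
    ok <- tryCatch({chol(cv); TRUE}, error = function(e) FALSE)
    if (!ok || rcond(cv) < 1e-12) {
      warnf("near-singular covariance for class %s; adding ridge", cl)
      cv <- cv + diag(1e-6 * mean(diag(cv)), p)
      ok <- tryCatch({chol(cv); TRUE}, error = function(e) FALSE)
      if (!ok) stopf("covariance for class %s is singular", cl)
    }
    means[[cl]] <- mu
    covs[[cl]] <- cv
  }
  if (is.null(priors)) {
    priors <- stats::setNames(rep(1 / length(classes), length(classes)),
                              classes)
  } else {
    priors <- priors[classes]
    if (anyNA(priors) || abs(sum(priors) - 1) > 1e-9)
      stopf("priors must cover every class and sum to 1")
  }
  new("GaussianClassModel", means = means, covs = covs, priors = priors,
      bandCount = p)
}

#' Maximum-likelihood weighted distance
#'
#' Evaluates D = ln(a_c) - 0.5 ln|Cov_c| - 0.5 Mahalanobis^2 for one class.
#' Larger D means the pixel is more likely to belong to the class.
#'
#' @param x feature vector (length = band count).
#' @param model a [GaussianClassModel-class].
#' @param class class name.
#' @return The weighted distance D (scalar).
#' @export
mlcDiscriminant <- function(x, model, class) {
  if (length(x) != model@bandCount)
    stopf("feature vector length %d != band count %d", length(x),
          model@bandCount)
  mu <- model@means[[class]]
  R <- chol(model@covs[[class]])
  logdet <- 2 * sum(log(diag(R)))
  z <- backsolve(R, x - mu, transpose = TRUE)
  log(model@priors[[class]]) - 0.5 * logdet - 0.5 * sum(z^2)
}

modelClassLabels <- function(model) {
  classes <- names(model@means)
  legend <- lulcLegend()
  if (all(classes %in% names(legend))) {
    legend[intersect(names(legend), classes)]
  } else {
    stats::setNames(seq_along(classes), classes)
  }
}

#' Classify a scene by maximum likelihood
#'
#' Labels every valid pixel with the class maximizing the weighted
#' distance D; ties resolve to the lowest class index and nodata pixels
#' get label 0. By default the thermal band is excluded from the feature
#' vector (the classifier operates on the reflective composite).
#'
#' @param scene a [RasterScene-class].
#' @param model a [GaussianClassModel-class].
#' @param bands band indices to use; default all bands except the thermal
#'   role.
#' @return A [ClassMap-class].
#' @export
classifyScene <- function(scene, model, bands = NULL) {
  d <- dim(scene@bands)
  if (is.null(bands))
    bands <- setdiff(seq_len(d[3]), scene@spec@bandRoles[["thermal"]])
  if (length(bands) != model@bandCount)
    stopf("model expects %d bands, scene provides %d", model@bandCount,
          length(bands))
  legend <- modelClassLabels(model)
  labels <- matrix(0L, d[1], d[2])
  valid <- which(scene@mask)
  if (length(valid)) {
    X <- vapply(bands, function(b) scene@bands[, , b][valid],
                numeric(length(valid)))
    X <- matrix(X, nrow = length(valid))
    classes <- names(model@means)
    D <- matrix(0, length(valid), length(classes))
    for (i in seq_along(classes)) {
      cl <- classes[i]
      R <- chol(model@covs[[cl]])
      logdet <- 2 * sum(log(diag(R)))
      diffs <- sweep(X, 2, model@means[[cl]])
      Z <- t(backsolve(R, t(diffs), transpose = TRUE))
      D[, i] <- log(model@priors[[cl]]) - 0.5 * logdet - 0.5 * rowSums(Z^2)
    }
    win <- max.col(D, ties.method = "first")
    labels[valid] <- as.integer(legend[classes[win]])
  }
  lg <- if (all(names(legend) %in% names(lulcLegend()))) lulcLegend()
        else legend
  classMap(labels, legend = lg, geotransform = scene@geotransform,
           crs = scene@crs, date = scene@date)
}

## Box (moving-window) sum via a summed-area table; edge windows truncate.
## S[i+1, j+1] holds sum(m[1:i, 1:j]).
boxSum <- function(m, half) {
  nr <- nrow(m); nc <- ncol(m)
  S <- matrix(0, nr + 1L, nc + 1L)
  cs <- apply(m, 2, cumsum)
  S[-1, -1] <- t(apply(cs, 1, cumsum))
  r0 <- pmax(seq_len(nr) - half, 1L); r1 <- pmin(seq_len(nr) + half, nr)
  c0 <- pmax(seq_len(nc) - half, 1L); c1 <- pmin(seq_len(nc) + half, nc)
  ri1 <- rep(r1 + 1L, times = nc); ri0 <- rep(r0, times = nc)
  ci1 <- rep(c1 + 1L, each = nr); ci0 <- rep(c0, each = nr)
  matrix(S[cbind(ri1, ci1)] - S[cbind(ri0, ci1)] -
           S[cbind(ri1, ci0)] + S[cbind(ri0, ci0)], nr, nc)
}

#' Majority (modal) filter for class maps
#'
#' Replaces each valid pixel by the modal label among valid pixels in its
#' window; a tie for the mode keeps the pixel's original label, and nodata
#' pixels are unchanged. Never introduces a label absent from the window.
#'
#' @param map a [ClassMap-class].
#' @param window odd window width >= 3.
#' @return The filtered [ClassMap-class].
#' @export
majorityFilter <- function(map, window = 3L) {
  if (window %% 2 == 0 || window < 3) stopf("window must be odd and >= 3")
  half <- (window - 1L) %/% 2L
  labels <- mapLabels(map)
  present <- sort(unique(labels[labels > 0L]))
  if (!length(present)) return(map)
  nr <- nrow(labels); nc <- ncol(labels)
  counts <- array(0, dim = c(nr, nc, length(present)))
  for (i in seq_along(present))
    counts[, , i] <- matrix(boxSum((labels == present[i]) * 1, half), nr, nc)
  flat <- matrix(counts, nr * nc, length(present))
  best <- apply(flat, 1, max)
  nBest <- rowSums(flat == best)
  winner <- present[max.col(flat, ties.method = "first")]
  out <- labels
  replace <- labels > 0L & matrix(nBest == 1L, nr, nc)
  out[replace] <- winner[which(replace)]
  classMap(out, legend = mapLegend(map), geotransform = geoTransform(map),
           crs = crsId(map), date = gridDate(map))
}
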