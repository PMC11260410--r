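## Stratified reference sampling and confusion-matrix accuracy metrics.
## Matrix orientation throughout: rows = classified map label,
## columns = reference label, so producer's accuracy divides by column
## totals (omission) and user's accuracy by row totals (commission).

#' Stratified random sample of a class map
#'
#' Allocates points proportionally to class pixel share with a floor of 5
#' per present class, using largest-remainder rounding so allocations sum
#' to `total`; sampling is without replacement within class and
#' deterministic for a fixed seed. If a class has fewer pixels than its
#' allocation, the allocation is reduced with a warning.
#'
#' @param map a [ClassMap-class].
#' @param total total number of points (default 600).
#' @param seed RNG seed.
#' @param floor minimum points per present class.
#' @return data.frame(row, col, mapLabel).
#' @export
stratifiedSample <- function(map, total = 600L, seed = 1L, floor = 5L) {
  labels <- mapLabels(map)
  valid <- which(labels > 0L)
  if (!length(valid)) stopf("map has no valid pixels")
  tab <- table(labels[valid])
  present <- as.integer(names(tab))
  k <- length(present)
  if (total < k) stopf("total must be at least the number of classes")
  share <- as.numeric(tab) / length(valid)
  base <- base::floor(share * total)
  rem <- share * total - base
  extra <- total - sum(base)
  if (extra > 0) {
    ord <- order(rem, decreasing = TRUE)
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1L
  }
  alloc <- base
  ## enforce floor, taking the deficit from the largest allocations
  deficit <- sum(pmax(floor - alloc, 0))
  alloc <- pmax(alloc, floor)
  while (deficit > 0) {
    i <- which.max(alloc)
    take <- min(deficit, alloc[i] - floor)
    if (take <= 0) break
    alloc[i] <- alloc[i] - take
    deficit <- deficit - take
  }
  over <- alloc > as.numeric(tab)
  if (any(over)) {
    warnf("allocation reduced for class(es) %s (fewer pixels than points)",
          paste(present[over], collapse = ", "))
    alloc[over] <- as.numeric(tab)[over]
  }
  set.seed(deriveSeed(seed, 5L))
  picks <- integer(0)
  for (i in seq_len(k)) {
    cand <- which(labels == present[i])
    picks <- c(picks, sample(cand, alloc[i]))
  }
  rc <- arrayInd(picks, dim(labels))
  data.frame(row = rc[, 1], col = rc[, 2],
             mapLabel = as.integer(labels[picks]))
}

#' Build a confusion matrix from labeled points
#'
#' Increments counts[map label, reference label] for each point; points
#' falling on nodata are excluded with a warning.
#'
#' @param points data.frame with columns row, col and refLabel.
#' @param map a [ClassMap-class].
#' @return A [ConfusionMatrix-class] over the map legend.
#' @export
buildConfusion <- function(points, map) {
  labels <- mapLabels(map)
  mapLab <- labels[cbind(points$row, points$col)]
  drop <- mapLab == 0L
  if (any(drop)) {
    warnf("%d point(s) on nodata excluded", sum(drop))
    mapLab <- mapLab[!drop]
    points <- points[!drop, , drop = FALSE]
  }
  legend <- mapLegend(map)
  counts <- table(factor(mapLab, levels = legend),
                  factor(points$refLabel, levels = legend))
  confusionMatrix(matrix(as.integer(counts), length(legend),
                         dimnames = list(names(legend), names(legend))),
                  classLabels = names(legend))
}

#' Overall accuracy
#'
#' OA = sum of diagonal counts / total count: the fraction of reference
#' points whose map label agrees with the reference label.
#'
#' @param cm a [ConfusionMatrix-class].
#' @return Fraction in [0, 1].
#' @export
overallAccuracy <- function(cm) {
  N <- sum(cm@counts)
  sum(diag(cm@counts)) / N
}

#' Producer's accuracy per class
#'
#' PA_i = counts[i, i] / column total i — the probability that a reference
#' pixel of class i is mapped as i (1 minus the omission error). NA where
#' the class is absent from the reference.
#'
#' @param cm a [ConfusionMatrix-class].
#' @return Named per-class fractions.
#' @export
producersAccuracy <- function(cm) {
  ct <- colSums(cm@counts)
  out <- diag(cm@counts) / ct
  out[ct == 0] <- NA_real_
  stats::setNames(out, cm@classLabels)
}

#' User's accuracy per class
#'
#' UA_i = counts[i, i] / row total i — the probability that a pixel mapped
#' as class i really is i (1 minus the commission error). NA where the
#' class is absent from the map.
#'
#' @param cm a [ConfusionMatrix-class].
#' @return Named per-class fractions.
#' @export
usersAccuracy <- function(cm) {
  rt <- rowSums(cm@counts)
  out <- diag(cm@counts) / rt
  out[rt == 0] <- NA_real_
  stats::setNames(out, cm@classLabels)
}

#' Kappa coefficient of agreement
#'
#' K = (N * sum(x_ii) - sum(x_i+ * x_+i)) / (N^2 - sum(x_i+ * x_+i)):
#' agreement corrected for the chance agreement implied by the marginal
#' totals. Returns NA when the denominator is zero.
#'
#' @param cm a [ConfusionMatrix-class].
#' @return Dimensionless value in [-1, 1].
#' @export
kappaCoefficient <- function(cm) {
  x <- cm@counts
  N <- sum(x)
  chance <- sum(rowSums(x) * colSums(x))
  denom <- N^2 - chance
  if (denom == 0) return(NA_real_)
  (N * sum(diag(x)) - chance) / denom
}

#' Full accuracy assessment
#'
#' Builds the confusion matrix from reference points and bundles OA,
#' per-class producer's/user's accuracy and kappa; `passesThreshold` is
#' TRUE when kappa meets the actionability threshold (default 0.75).
#'
#' @param map a [ClassMap-class].
#' @param points data.frame(row, col, refLabel).
#' @param threshold kappa threshold.
#' @return An [AccuracyReport-class].
#' @export
assessAccuracy <- function(map, points, threshold = 0.75) {
  cm <- buildConfusion(points, map)
  k <- kappaCoefficient(cm)
  new("AccuracyReport",
      overallAccuracy = overallAccuracy(cm),
      producersAccuracy = producersAccuracy(cm),
      usersAccuracy = usersAccuracy(cm),
      kappa = k, nPoints = as.integer(sum(cm@counts)),
      threshold = threshold,
      passesThreshold = isTRUE(k >= threshold))
}
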