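## Change detection: cross-tabulation of two class maps into a transition
## area matrix (km2) and per-class gain/loss/net accounting. Pixels nodata
## in either date are excluded from both, which keeps the conservation
## laws (row sums = date-1 areas, column sums = date-2 areas,
## sum of gains = sum of losses) exact.

#' Cross-tabulate two class maps
#'
#' Cell (i, j) holds the area (km2) classified i at date 1 and j at
#' date 2. Both maps must share shape, geotransform and legend.
#'
#' @param map1,map2 [ClassMap-class] objects for the two dates.
#' @return A [ChangeMatrix-class].
#' @export
crosstab <- function(map1, map2) {
  if (!identical(dim(mapLabels(map1)), dim(mapLabels(map2))) ||
      !isTRUE(all.equal(geoTransform(map1), geoTransform(map2))) ||
      !identical(mapLegend(map1), mapLegend(map2)))
    stopf("maps are not aligned (shape, geotransform or legend differ)")
  l1 <- mapLabels(map1); l2 <- mapLabels(map2)
  both <- l1 > 0L & l2 > 0L
  legend <- mapLegend(map1)
  counts <- table(factor(l1[both], levels = legend),
                  factor(l2[both], levels = legend))
  pa <- pixelAreaKm2(map1)
  areas <- matrix(as.numeric(counts), length(legend), length(legend),
                  dimnames = list(names(legend), names(legend))) * pa
  new("ChangeMatrix", areasKm2 = areas,
      datePair = c(gridDate(map1), gridDate(map2)),
      pixelAreaKm2 = pa, classLabels = names(legend))
}

#' Gain, loss and net change per class
#'
#' gain = column total - diagonal (area that became the class),
#' loss = row total - diagonal (area the class lost),
#' net = gain - loss = date-2 area - date-1 area.
#'
#' @param cm a [ChangeMatrix-class].
#' @param class optional class code; default all classes.
#' @return data.frame(class, gainKm2, lossKm2, netKm2).
#' @export
gainLossNet <- function(cm, class = NULL) {
  a <- cm@areasKm2
  d <- diag(a)
  out <- data.frame(class = cm@classLabels,
                    gainKm2 = colSums(a) - d,
                    lossKm2 = rowSums(a) - d)
  out$netKm2 <- out$gainKm2 - out$lossKm2
  rownames(out) <- NULL
  if (!is.null(class)) {
    if (!class %in% out$class) stopf("class %s not in legend", class)
    out <- out[out$class == class, , drop = FALSE]
  }
  out
}

#' Per-class area summary of a class map
#'
#' Areas in km2 (2 decimals) and percent of the denominator (1 decimal);
#' the denominator is the supplied total geographic area if given, else
#' the valid mapped area.
#'
#' @param map a [ClassMap-class].
#' @param totalAreaKm2 optional fixed percent denominator.
#' @return data.frame(class, areaKm2, percent).
#' @export
areaSummary <- function(map, totalAreaKm2 = NULL) {
  labels <- mapLabels(map)
  valid <- labels > 0L
  if (!any(valid)) stopf("map has no valid pixels")
  legend <- mapLegend(map)
  counts <- table(factor(labels[valid], levels = legend))
  areas <- as.numeric(counts) * pixelAreaKm2(map)
  denom <- if (is.null(totalAreaKm2)) sum(areas) else totalAreaKm2
  data.frame(class = names(legend),
             areaKm2 = round(areas, 2),
             percent = round(100 * areas / denom, 1))
}
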