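# Internal helpers shared across modules.

#' Land-use/land-cover legend
#'
#' The five-class legend used throughout the package: forest (FC),
#' agriculture (AG), built-up/settlements (BS), water bodies (WB) and
#' other (OT). Label 0 is reserved for nodata.
#'
#' @return Named integer vector mapping class code to label.
#' @export
#' @examples
#' lulcLegend()
lulcLegend <- function() {
  c(FC = 1L, AG = 2L, BS = 3L, WB = 4L, OT = 5L)
}

## GDAL-style geotransform: c(xmin, px, 0, ymax, 0, -py).
makeGeotransform <- function(pixelSize, xmin = 0, ymax = NULL, nrow = NULL) {
  if (is.null(ymax)) ymax <- nrow * pixelSize
  c(xmin, pixelSize, 0, ymax, 0, -pixelSize)
}

gtPixelSize <- function(gt) c(gt[2], -gt[6])

## Centers of pixel (i, j) (1-based row, col) in map coordinates.
pixelCenters <- function(gt, rows, cols) {
  x <- gt[1] + (cols - 0.5) * gt[2]
  y <- gt[4] + (rows - 0.5) * gt[6]
  cbind(x = x, y = y)
}

## Dense Toeplitz smoothing matrix with Gaussian weights, rows normalized so
## edges are handled exactly (no padding artefacts).
smoothingMatrix <- function(n, sigma) {
  idx <- seq_len(n)
  S <- outer(idx, idx, function(i, j) stats::dnorm(i - j, sd = sigma))
  S / rowSums(S)
}

## Separable Gaussian smoothing of a matrix.
gaussianSmooth <- function(x, sigma) {
  Sr <- smoothingMatrix(nrow(x), sigma)
  Sc <- smoothingMatrix(ncol(x), sigma)
  Sr %*% x %*% t(Sc)
}

## Even-odd (ray casting) point-in-polygon test. `pts` is a 2-column matrix of
## x,y; `poly` a 2-column matrix of vertices (closed or open ring).
pointsInPolygon <- function(pts, poly) {
  px <- poly[, 1]; py <- poly[, 2]
  n <- nrow(poly)
  if (px[1] == px[n] && py[1] == py[n]) { # drop duplicated closing vertex
    px <- px[-n]; py <- py[-n]; n <- n - 1L
  }
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    xi <- px[i]; yi <- py[i]; xj <- px[j]; yj <- py[j]
    cross <- ((yi > pts[, 2]) != (yj > pts[, 2])) &
      (pts[, 1] < (xj - xi) * (pts[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

## Deterministic per-purpose seed derivation, kept well inside 32-bit range.
deriveSeed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
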