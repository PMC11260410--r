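## Plain-text raster I/O.
##
## Grids are stored as ESRI ASCII grid (.asc) files — one per band for
## multi-band scenes — with a JSON sidecar carrying the CRS identifier,
## date, processing stage and the sensor calibration spec. The format is
## text-based, widely understood by GIS software, and loss-controlled:
## float values are written with 9 significant digits (full float32
## precision), byte/label grids exactly.

#' Write a matrix as an ESRI ASCII grid
#'
#' @param values numeric matrix (row 1 = northernmost row); NA written as
#'   the nodata value.
#' @param geotransform affine geotransform of the grid (square pixels).
#' @param path output file path.
#' @param nodata nodata sentinel written for NA cells.
#' @return `path`, invisibly.
#' @export
writeAsciiGrid <- function(values, geotransform, path, nodata = -9999) {
  ps <- gtPixelSize(geotransform)
  if (abs(ps[1] - ps[2]) > 1e-9)
    stopf("ASCII grid requires square pixels")
  nr <- nrow(values); nc <- ncol(values)
  yll <- geotransform[4] - nr * ps[2]
  hdr <- c(sprintf("ncols %d", nc), sprintf("nrows %d", nr),
           sprintf("xllcorner %.10g", geotransform[1]),
           sprintf("yllcorner %.10g", yll),
           sprintf("cellsize %.10g", ps[1]),
           sprintf("NODATA_value %.10g", nodata))
  v <- values
  v[is.na(v)] <- nodata
  body <- apply(v, 1, function(row)
    paste(formatC(row, format = "g", digits = 9), collapse = " "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file path.
#' @return list with `values` (matrix, NA at nodata) and `geotransform`.
#' @export
readAsciiGrid <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  hdr <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1))
  vals <- as.numeric(vapply(kv, `[`, "", 2))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% keys))
    stopf("%s is not an ESRI ASCII grid (missing georeferencing header)",
          path)
  nc <- as.integer(vals[["ncols"]]); nr <- as.integer(vals[["nrows"]])
  nodata <- if ("nodata_value" %in% keys) vals[["nodata_value"]] else NA
  raw <- scan(path, skip = 6, quiet = TRUE)
  if (length(raw) != nr * nc) stopf("corrupt grid body in %s", path)
  m <- matrix(raw, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.na(nodata)) m[m == nodata] <- NA
  gt <- c(vals[["xllcorner"]], vals[["cellsize"]], 0,
          vals[["yllcorner"]] + nr * vals[["cellsize"]], 0,
          -vals[["cellsize"]])
  list(values = m, geotransform = gt)
}

specToList <- function(spec) {
  list(sensorId = spec@sensorId, bandRoles = as.list(spec@bandRoles),
       gain = spec@gain, offset = spec@offset, K1 = spec@K1, K2 = spec@K2,
       lambdaUm = spec@lambdaUm)
}

specFromList <- function(x) {
  sensorSpec(x$sensorId, unlist(x$bandRoles), unlist(x$gain),
             unlist(x$offset), x$K1, x$K2, x$lambdaUm)
}

#' Write a multi-band scene
#'
#' Writes one ASCII grid per band (`<base>_b<i>.asc`, nodata pixels set to
#' the nodata sentinel) and a `<base>.json` sidecar with stage, CRS, date
#' and the sensor spec.
#'
#' @param scene a [RasterScene-class].
#' @param base output path prefix (no extension).
#' @return `base`, invisibly.
#' @export
writeScene <- function(scene, base) {
  d <- dim(scene@bands)
  for (b in seq_len(d[3])) {
    v <- scene@bands[, , b]
    v[!scene@mask] <- NA
    writeAsciiGrid(v, scene@geotransform, sprintf("%s_b%d.asc", base, b))
  }
  meta <- list(nBands = d[3], stage = scene@stage, crs = scene@crs,
               date = scene@date, spec = specToList(scene@spec))
  jsonlite::write_json(meta, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(base)
}

#' Read a multi-band scene written by [writeScene()]
#'
#' @param base path prefix used at write time.
#' @return A [RasterScene-class]; the mask is reconstructed from nodata.
#' @export
readScene <- function(base) {
  metaPath <- paste0(base, ".json")
  if (!file.exists(metaPath)) stopf("missing scene sidecar: %s", metaPath)
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  nb <- as.integer(meta$nBands)
  grids <- lapply(seq_len(nb), function(b)
    readAsciiGrid(sprintf("%s_b%d.asc", base, b)))
  d <- dim(grids[[1]]$values)
  bands <- array(0, dim = c(d[1], d[2], nb))
  mask <- matrix(TRUE, d[1], d[2])
  for (b in seq_len(nb)) {
    v <- grids[[b]]$values
    mask <- mask & !is.na(v)
    v[is.na(v)] <- 0
    bands[, , b] <- v
  }
  rasterScene(bands, mask = mask, stage = meta$stage,
              spec = specFromList(meta$spec),
              geotransform = grids[[1]]$geotransform,
              crs = meta$crs, date = meta$date)
}

#' Write a data frame as a CSV table
#'
#' @param rows a data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTable <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
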