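## On-disk raster format
##
## No GeoTIFF tag writer is available to this package, so rasters are
## stored as the classic "TIFF + world file" pair used throughout GIS:
##   <path>       single-band 32-bit TIFF; cell values affinely rescaled
##                to [0.25, 1], nodata cells stored as exactly 0
##   <path>.tfw   6-line ESRI world file (pixel sizes + centre of the
##                top-left pixel), north-up convention
##   <path>.aux.json  value scale/offset, nodata sentinel, units, CRS
## The rescaling is lossless to ~2e-10 of the value range (32-bit depth).

.LOW <- 0.25 # lowest code used for real data; 0 is reserved for nodata

.worldFilePath <- function(path) paste0(path, ".tfw")
.auxFilePath <- function(path) paste0(path, ".aux.json")

#' Write a raster to disk
#'
#' Writes a \linkS4class{RasterGrid} as a single-band 32-bit TIFF with an
#' ESRI world file (\code{.tfw}) carrying the affine transform and a JSON
#' sidecar carrying the value scaling, nodata sentinel, units and CRS.
#' \code{readRaster} restores values, transform and nodata exactly (to
#' 32-bit quantization, about 2e-10 of the value range).
#'
#' @param grid a \linkS4class{RasterGrid}.
#' @param path output file path (conventionally \code{.tif}).
#' @return \code{path}, invisibly.
#' @seealso [readRaster()]
#' @examples
#' g <- rasterGrid(matrix(rnorm(200), 10), pixelSize = 0.5, units = "m")
#' f <- tempfile(fileext = ".tif")
#' writeRaster(g, f)
#' g2 <- readRaster(f)
#' max(abs(gridValues(g) - gridValues(g2)))
#' @export
writeRaster <- function(grid, path) {
  stopifnot(is(grid, "RasterGrid"))
  validObject(grid)
  v <- grid@values
  ok <- !is.na(v)
  if (!any(ok)) {
    warning("writing an all-nodata raster: ", path)
    lo <- 0; hi <- 1
  } else {
    lo <- min(v[ok]); hi <- max(v[ok])
    if (hi == lo) hi <- lo + 1
  }
  coded <- matrix(0, nrow(v), ncol(v))
  coded[ok] <- .LOW + (1 - .LOW) * (v[ok] - lo) / (hi - lo)
  okWrite <- tryCatch({
    tiff::writeTIFF(coded, path, bits.per.sample = 32L, compression = "none")
    TRUE
  }, error = function(e) FALSE)
  if (!okWrite) stop("cannot write raster file: ", path)
  tfw <- c(grid@pixelSizeX, 0, 0, -grid@pixelSizeY,
           grid@xmin + grid@pixelSizeX / 2,
           grid@ymax - grid@pixelSizeY / 2)
  writeLines(formatC(tfw, format = "g", digits = 17), .worldFilePath(path))
  jsonlite::write_json(
    list(value_offset = lo, value_scale = (hi - lo) / (1 - .LOW),
         low_code = .LOW, nodata = grid@nodata,
         units = grid@units, crs = grid@crs),
    .auxFilePath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a raster from disk
#'
#' Reads a raster written by \code{\link{writeRaster}} (single-band 32-bit
#' TIFF + world file + JSON sidecar). Nodata cells come back as \code{NA};
#' rasters whose sidecar declares a geographic (degree-unit) CRS are
#' rejected, as all downstream arithmetic assumes metres.
#'
#' @param path file path.
#' @param band band index for multi-band files; reading a multi-band file
#'   without selecting a band is an error.
#' @return a \linkS4class{RasterGrid}.
#' @export
readRaster <- function(path, band = NULL) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  img <- tiff::readTIFF(path, all = TRUE)
  if (length(img) > 1L)
    stop("multi-page TIFF: select one with 'band'")
  img <- img[[1L]]
  if (length(dim(img)) == 3L) {
    if (is.null(band))
      stop("multi-band file '", path, "': select a band with 'band'")
    img <- img[, , band]
  }
  tfwPath <- .worldFilePath(path)
  if (file.exists(tfwPath)) {
    tfw <- as.numeric(readLines(tfwPath))
    if (length(tfw) != 6L || any(is.na(tfw)))
      stop("malformed world file: ", tfwPath)
    if (tfw[2] != 0 || tfw[3] != 0)
      stop("rotated grids are not supported: ", tfwPath)
    psx <- tfw[1]; psy <- -tfw[4]
    if (psx <= 0 || psy <= 0)
      stop("expected a north-up grid (pixel x size > 0, y size < 0)")
    xmin <- tfw[5] - psx / 2
    ymax <- tfw[6] + psy / 2
  } else {
    psx <- psy <- 1; xmin <- 0; ymax <- nrow(img)
  }
  auxPath <- .auxFilePath(path)
  if (file.exists(auxPath)) {
    aux <- jsonlite::read_json(auxPath, simplifyVector = TRUE)
  } else {
    aux <- list(value_offset = 0, value_scale = 1 / (1 - .LOW),
                low_code = .LOW, nodata = -9999, units = "", crs = "local-metric")
  }
  if (.isGeographicCrs(aux$crs))
    stop("raster '", path, "' is in a geographic (degree-unit) CRS; ",
         "a projected metric CRS is required")
  v <- matrix(NA_real_, nrow(img), ncol(img))
  ok <- img >= aux$low_code / 2
  v[ok] <- aux$value_offset + (img[ok] - aux$low_code) * aux$value_scale
  rasterGrid(v, xmin = xmin, ymax = ymax, pixelSize = c(psx, psy),
             nodata = aux$nodata, units = aux$units, crs = aux$crs)
}
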