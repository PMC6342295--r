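## NDVI map algebra and leaf-level spectral conversions.
##
## Band note: NIR is the 760-900 nm band and RED the 630-690 nm band.
## Inputs are assumed to be reflectances in [0, 1]; no radiometric
## calibration is applied here.

#' NDVI from reflectance bands
#'
#' Pixelwise normalized difference vegetation index,
#' \code{(NIR - RED) / (NIR + RED)}. Pixels where both bands are zero
#' (no signal) become nodata rather than NaN; nodata in either band
#' propagates.
#'
#' @param nir,red aligned \linkS4class{RasterGrid}s of reflectance in
#'   [0, 1].
#' @return a \linkS4class{RasterGrid} with values in [-1, 1], units
#'   "ndvi".
#' @examples
#' nirG <- rasterGrid(matrix(0.4, 2, 2)); redG <- rasterGrid(matrix(0.1, 2, 2))
#' gridValues(ndvi(nirG, redG))[1] # 0.6
#' @export
ndvi <- function(nir, red) {
  .checkAligned(nir, red, "NIR and RED")
  a <- gridValues(nir); b <- gridValues(red)
  bad <- c(a[!is.na(a)], b[!is.na(b)])
  if (length(bad) && (min(bad) < 0 || max(bad) > 1))
    stop("reflectance values outside [0, 1]")
  s <- a + b
  v <- ifelse(!is.na(s) & s > 0, (a - b) / s, NA_real_)
  withValues(nir, v, units = "ndvi")
}

#' Mean NDVI over a crown segment
#'
#' @param ndviGrid \linkS4class{RasterGrid} of NDVI values.
#' @param segments a \linkS4class{CrownSegmentSet} on the same grid.
#' @param label segment label.
#' @return mean of the non-nodata NDVI pixels under the segment mask.
#' @export
perTreeNdvi <- function(ndviGrid, segments, label) {
  .checkAligned(ndviGrid, labelRaster(segments), "NDVI and segment labels")
  v <- gridValues(ndviGrid)[segmentMask(segments, label)]
  v <- v[!is.na(v)]
  if (!length(v)) stop("segment ", label, " has no valid NDVI pixels")
  mean(v)
}

#' Leaf chlorophyll from SPAD readings
#'
#' Converts the SPAD greenness index to total chlorophyll a+b
#' concentration with the calibration \code{Cab = 0.8271 * SPAD - 12.8}
#' (ug cm^-2). Readings low enough to give a negative concentration are
#' outside the calibration domain and returned as-is with a warning.
#'
#' @param spad SPAD readings, >= 0.
#' @return chlorophyll a+b concentration, ug cm^-2.
#' @examples
#' spadToCab(50) # 28.555
#' @export
spadToCab <- function(spad) {
  if (any(spad < 0)) stop("SPAD readings must be >= 0")
  cab <- 0.8271 * spad - 12.8
  if (any(cab < 0))
    warning("SPAD reading(s) below the calibration domain ",
            "(Cab < 0 ug cm^-2) returned unmodified")
  cab
}
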