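#' @import methods
NULL

#' Georeferenced raster grid
#'
#' A single-band, north-up raster in a projected coordinate system with
#' metres as units. The affine transform is restricted to the axis-aligned
#' case: pixel (row, col) has its *centre* at
#' \code{x = xmin + (col - 0.5) * pixelSizeX},
#' \code{y = ymax - (row - 0.5) * pixelSizeY}; row 1 is the northernmost
#' row. Missing cells are stored as \code{NA} in \code{values}; the
#' \code{nodata} slot records the sentinel used on disk.
#'
#' @slot values numeric matrix of cell values (\code{NA} = nodata).
#' @slot xmin x coordinate (m) of the west edge of the grid.
#' @slot ymax y coordinate (m) of the north edge of the grid.
#' @slot pixelSizeX,pixelSizeY cell size (m), both > 0.
#' @slot nodata numeric sentinel written to disk for missing cells.
#' @slot units free-text label for the cell values ("m", "reflectance",
#'   "ndvi", ...).
#' @slot crs coordinate reference system label; must describe a projected,
#'   metre-based system (anything containing "degree", "longlat" or
#'   "EPSG:4326" is rejected).
#'
#' @examples
#' g <- rasterGrid(matrix(1:12, 3), pixelSize = 0.5)
#' pixelArea(g)
#' @export
setClass("RasterGrid",
  representation(
    values = "matrix",
    xmin = "numeric",
    ymax = "numeric",
    pixelSizeX = "numeric",
    pixelSizeY = "numeric",
    nodata = "numeric",
    units = "character",
    crs = "character"
  ),
  prototype(
    xmin = 0, ymax = 0, pixelSizeX = 1, pixelSizeY = 1,
    nodata = -9999, units = "", crs = "local-metric"
  )
)

.isGeographicCrs <- function(crs) {
  grepl("degree|longlat|4326|geographic", crs, ignore.case = TRUE)
}

setValidity("RasterGrid", function(object) {
  msg <- character()
  if (!is.numeric(object@values))
    msg <- c(msg, "'values' must be a numeric matrix")
  if (length(object@pixelSizeX) != 1L || object@pixelSizeX <= 0 ||
      length(object@pixelSizeY) != 1L || object@pixelSizeY <= 0)
    msg <- c(msg, "pixel sizes must be positive scalars")
  if (.isGeographicCrs(object@crs))
    msg <- c(msg, "geographic (degree-unit) CRS not supported; use a projected metric CRS")
  if (any(object@values == object@nodata, na.rm = TRUE))
    msg <- c(msg, "in-memory values must use NA, not the nodata sentinel")
  if (length(msg)) msg else TRUE
})

#' Delineated tree crowns
#'
#' The result of connected-component labelling of a binary crown mask:
#' an integer label raster aligned with the input grid (0 = background)
#' plus a per-segment table with footprint area and centroid. Labels are
#' assigned in raster-scan order of each component's top-left pixel.
#'
#' @slot labels \code{RasterGrid} of integer labels (0 = background).
#' @slot table data.frame with columns \code{label}, \code{n_pixels},
#'   \code{footprint_area} (m^2), \code{centroid_x}, \code{centroid_y} (m),
#'   \code{row_min}, \code{row_max}, \code{col_min}, \code{col_max}.
#' @export
setClass("CrownSegmentSet",
  representation(labels = "RasterGrid", table = "data.frame")
)

setValidity("CrownSegmentSet", function(object) {
  tab <- object@table
  need <- c("label", "n_pixels", "footprint_area", "centroid_x", "centroid_y")
  if (!all(need %in% names(tab)))
    return(paste("segment table must have columns:", paste(need, collapse = ", ")))
  if (nrow(tab) && any(duplicated(tab$label)))
    return("duplicate segment labels")
  TRUE
})

#' Stem water potential time series
#'
#' Dated midday stem water potential (SWP) measurements for one tree or
#' treatment. SWP is a tension, hence always <= 0 MPa; days of year must
#' be strictly increasing.
#'
#' @slot treeId identifier of the tree or treatment.
#' @slot doy integer day-of-year of each measurement, strictly increasing.
#' @slot swp numeric SWP (MPa, <= 0), same length as \code{doy}.
#' @export
setClass("SWPSeries",
  representation(treeId = "character", doy = "integer", swp = "numeric"),
  prototype(treeId = "tree")
)

setValidity("SWPSeries", function(object) {
  if (length(object@doy) != length(object@swp))
    return("doy and swp must have the same length")
  if (length(object@doy) > 1L && any(diff(object@doy) <= 0L))
    return("doy must be strictly increasing")
  if (any(object@swp > 0))
    return("SWP values must be <= 0 MPa")
  TRUE
})

#' Water stress integral result
#'
#' Accumulated deviation of stem water potential from its seasonal maximum
#' (Myers' water stress integral). \code{wsi} is reported positive in
#' MPa d; \code{dailyWsi = -wsi / nDays} is the signed daily mean (MPa).
#'
#' @slot wsi water stress integral, MPa d, >= 0.
#' @slot dailyWsi signed daily stress, MPa, <= 0.
#' @slot nDays days spanned by the records used.
#' @slot cRef reference SWP: the seasonal maximum (least negative) within
#'   the analysis window, MPa.
#' @slot n number of measurements used.
#' @export
setClass("WSIResult",
  representation(wsi = "numeric", dailyWsi = "numeric", nDays = "numeric",
                 cRef = "numeric", n = "integer")
)

#' Regression fit summary
#'
#' Container for the fits used to validate image-based estimates against
#' field measurements: origin-forced and ordinary simple regression,
#' continuous two-segment (bilinear, breakpoint) regression, and
#' two-predictor multiple regression.
#'
#' @slot model one of "origin_forced", "ordinary", "bilinear", "multiple".
#' @slot coefficients named numeric vector of fitted coefficients.
#' @slot breakpoint breakpoint location (bilinear model), else \code{NA}.
#' @slot breakpointIdentifiable \code{FALSE} when the profiled SSE is flat
#'   (the data are a single line), else \code{TRUE}.
#' @slot r2 coefficient of determination (uncentered for origin-forced
#'   fits, see \code{r2Type}).
#' @slot r2Type "centered" or "uncentered".
#' @slot rmse root mean square error of residuals (response units).
#' @slot n number of observations.
#' @export
setClass("RegressionResult",
  representation(model = "character", coefficients = "numeric",
                 breakpoint = "numeric", breakpointIdentifiable = "logical",
                 r2 = "numeric", r2Type = "character", rmse = "numeric",
                 n = "integer"),
  prototype(breakpoint = NA_real_, breakpointIdentifiable = TRUE,
            r2Type = "centered")
)

setValidity("RegressionResult", function(object) {
  if (length(object@rmse) == 1L && !is.na(object@rmse) && object@rmse < 0)
    return("rmse must be >= 0")
  TRUE
})
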