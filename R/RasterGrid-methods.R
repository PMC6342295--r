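#' Create a RasterGrid
#'
#' @param values numeric matrix; \code{NA} marks missing cells.
#' @param xmin,ymax world coordinates (m) of the west and north grid edges.
#'   By default the grid is anchored at the origin with \code{ymax} chosen
#'   so the south edge sits at y = 0.
#' @param pixelSize cell size in metres; a scalar or \code{c(x, y)}.
#' @param nodata sentinel value used when the grid is written to disk.
#' @param units free-text label for the cell values.
#' @param crs projected CRS label (degree-based systems are rejected).
#' @return a \linkS4class{RasterGrid}.
#' @examples
#' g <- rasterGrid(matrix(0, 50, 80), pixelSize = 0.02, units = "m")
#' gridExtent(g)
#' @export
rasterGrid <- function(values, xmin = 0, ymax = NULL, pixelSize = 1,
                       nodata = -9999, units = "", crs = "local-metric") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  psx <- pixelSize[[1L]]
  psy <- if (length(pixelSize) > 1L) pixelSize[[2L]] else pixelSize[[1L]]
  if (is.null(ymax)) ymax <- nrow(values) * psy
  values[!is.na(values) & values == nodata] <- NA_real_
  new("RasterGrid", values = values, xmin = xmin, ymax = ymax,
      pixelSizeX = psx, pixelSizeY = psy, nodata = nodata,
      units = units, crs = crs)
}

#' Accessors for RasterGrid
#'
#' \code{gridValues} returns the value matrix (\code{NA} = nodata);
#' \code{pixelSize} the \code{c(x, y)} cell size in metres; \code{pixelArea}
#' the cell area in m^2; \code{gridExtent} the named vector
#' \code{(xmin, xmax, ymin, ymax)}; \code{cellCoordinates} a list with the
#' world x of each column centre and world y of each row centre.
#'
#' @param x a \linkS4class{RasterGrid}.
#' @name RasterGrid-accessors
#' @aliases gridValues pixelSize pixelArea gridExtent gridUnits gridCrs
#'   cellCoordinates
NULL

#' @rdname RasterGrid-accessors
#' @export
setMethod("gridValues", "RasterGrid", function(x) x@values)

#' @rdname RasterGrid-accessors
#' @export
setMethod("pixelSize", "RasterGrid",
          function(x) c(x = x@pixelSizeX, y = x@pixelSizeY))

#' @rdname RasterGrid-accessors
#' @export
setMethod("pixelArea", "RasterGrid", function(x) x@pixelSizeX * x@pixelSizeY)

#' @rdname RasterGrid-accessors
#' @export
setMethod("gridExtent", "RasterGrid", function(x) {
  c(xmin = x@xmin, xmax = x@xmin + ncol(x@values) * x@pixelSizeX,
    ymin = x@ymax - nrow(x@values) * x@pixelSizeY, ymax = x@ymax)
})

#' @rdname RasterGrid-accessors
#' @export
setMethod("gridUnits", "RasterGrid", function(x) x@units)

#' @rdname RasterGrid-accessors
#' @export
setMethod("gridCrs", "RasterGrid", function(x) x@crs)

#' @rdname RasterGrid-accessors
#' @export
setMethod("cellCoordinates", "RasterGrid", function(x) {
  list(x = x@xmin + (seq_len(ncol(x@values)) - 0.5) * x@pixelSizeX,
       y = x@ymax - (seq_len(nrow(x@values)) - 0.5) * x@pixelSizeY)
})

#' @export
setMethod("dim", "RasterGrid", function(x) dim(x@values))

setMethod("show", "RasterGrid", function(object) {
  v <- object@values
  cat("RasterGrid:", nrow(v), "x", ncol(v), "cells,",
      signif(object@pixelSizeX, 4), "x", signif(object@pixelSizeY, 4), "m\n")
  ext <- gridExtent(object)
  cat("  extent  : x [", ext["xmin"], ",", ext["xmax"], "]  y [",
      ext["ymin"], ",", ext["ymax"], "] m\n")
  cat("  units   :", if (nzchar(object@units)) object@units else "<unset>",
      " crs:", object@crs, "\n")
  ok <- !is.na(v)
  if (any(ok)) {
    cat("  values  : [", signif(min(v[ok]), 6), ",", signif(max(v[ok]), 6),
        "]  nodata cells:", sum(!ok), "\n")
  } else {
    cat("  values  : all nodata\n")
  }
})

.sameGeometry <- function(a, b, tol = 1e-9) {
  all(dim(a@values) == dim(b@values)) &&
    abs(a@xmin - b@xmin) < tol && abs(a@ymax - b@ymax) < tol &&
    abs(a@pixelSizeX - b@pixelSizeX) < tol &&
    abs(a@pixelSizeY - b@pixelSizeY) < tol
}

.checkAligned <- function(a, b, what = "rasters") {
  if (!.sameGeometry(a, b))
    stop(what, " are not aligned (dimensions or transform differ)")
  invisible(TRUE)
}

#' Replace the value matrix of a grid, keeping its georeferencing
#'
#' @param grid a \linkS4class{RasterGrid} template.
#' @param values matrix with the same dimensions as \code{grid}.
#' @param units optional new units label.
#' @return a \linkS4class{RasterGrid}.
#' @export
withValues <- function(grid, values, units = grid@units) {
  stopifnot(all(dim(values) == dim(grid@values)))
  storage.mode(values) <- "double"
  initialize(grid, values = values, units = units)
}
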