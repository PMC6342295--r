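#' @rdname RasterGrid-accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname RasterGrid-accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname RasterGrid-accessors
#' @export
setGeneric("pixelArea", function(x) standardGeneric("pixelArea"))

#' @rdname RasterGrid-accessors
#' @export
setGeneric("gridExtent", function(x) standardGeneric("gridExtent"))

#' @rdname RasterGrid-accessors
#' @export
setGeneric("gridUnits", function(x) standardGeneric("gridUnits"))

#' @rdname RasterGrid-accessors
#' @export
setGeneric("gridCrs", function(x) standardGeneric("gridCrs"))

#' @rdname RasterGrid-accessors
#' @export
setGeneric("cellCoordinates", function(x) standardGeneric("cellCoordinates"))

#' @rdname CrownSegmentSet-accessors
#' @export
setGeneric("segmentTable", function(x) standardGeneric("segmentTable"))

#' @rdname CrownSegmentSet-accessors
#' @export
setGeneric("labelRaster", function(x) standardGeneric("labelRaster"))

#' @rdname CrownSegmentSet-accessors
#' @export
setGeneric("segmentMask", function(x, label) standardGeneric("segmentMask"))
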