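## Per-tree geometric traits from the nDSM and crown segments, plus the
## field-method formulas (ellipsoid canopy volume, TCSA) they are
## validated against.

#' Per-tree height from DSM and DTM
#'
#' Tree height is the maximum surface elevation over the crown segment
#' minus the average bare-ground elevation in an annulus of width
#' \code{ringWidth} around the segment, excluding all crown pixels (of
#' any tree) from the terrain average.
#'
#' @param dsm,dtm aligned \linkS4class{RasterGrid}s (m).
#' @param segments a \linkS4class{CrownSegmentSet} on the same grid.
#' @param label segment label to measure.
#' @param ringWidth annulus width (m) for the terrain average.
#' @return height in metres.
#' @export
treeHeight <- function(dsm, dtm, segments, label, ringWidth = 2) {
  .checkAligned(dsm, dtm, "DSM and DTM")
  .checkAligned(dsm, labelRaster(segments), "DSM and segment labels")
  lab <- gridValues(labelRaster(segments))
  mask <- lab == label
  if (!any(mask)) stop("segment ", label, " is empty")
  rad <- max(1L, round(ringWidth / dsm@pixelSizeX))
  # work on a window around the segment: the annulus cannot extend
  # further than the dilation radius
  idx <- which(mask, arr.ind = TRUE)
  ri <- max(1L, min(idx[, 1]) - rad):min(nrow(mask), max(idx[, 1]) + rad)
  ci <- max(1L, min(idx[, 2]) - rad):min(ncol(mask), max(idx[, 2]) + rad)
  maskW <- mask[ri, ci, drop = FALSE]
  labW <- lab[ri, ci, drop = FALSE]
  ring <- .dilateMask(maskW, rad) & !(labW > 0)
  dt <- gridValues(dtm)[ri, ci, drop = FALSE][ring]
  dt <- dt[!is.na(dt)]
  if (!length(dt))
    stop("empty terrain annulus around segment ", label)
  apex <- max(gridValues(dsm)[mask], na.rm = TRUE)
  apex - mean(dt)
}

#' Equivalent-circle crown diameter
#'
#' Under the assumption that the crown seen from above is circular, the
#' diameter follows from the projected footprint area:
#' \code{D = 2 * sqrt(area / pi)}. For an elliptic footprint with
#' semi-axes a, b this returns the geometric-mean diameter
#' \code{2 * sqrt(a * b)}.
#'
#' @param footprintArea projected crown area (m^2), > 0.
#' @return diameter in metres.
#' @examples
#' crownDiameter(pi * 1.5^2) # 3 m
#' @export
crownDiameter <- function(footprintArea) {
  if (any(footprintArea <= 0)) stop("footprint area must be > 0")
  2 * sqrt(footprintArea / pi)
}

#' Total (ground-to-surface) per-tree volume
#'
#' Integrates the canopy height model over the crown footprint: each
#' pixel contributes its area times its height above ground, and the
#' pixel volumes are summed over the segment. Nodata pixels inside the
#' segment are excluded with a warning.
#'
#' @param ndsm \linkS4class{RasterGrid} of heights above ground (m).
#' @param segments a \linkS4class{CrownSegmentSet} on the same grid.
#' @param label segment label.
#' @return volume in m^3.
#' @export
totalVolume <- function(ndsm, segments, label) {
  .checkAligned(ndsm, labelRaster(segments), "nDSM and segment labels")
  mask <- segmentMask(segments, label)
  h <- gridValues(ndsm)[mask]
  if (anyNA(h)) {
    warning(sum(is.na(h)), " nodata pixels inside segment ", label,
            " excluded from the volume sum")
    h <- h[!is.na(h)]
  }
  sum(h) * pixelArea(ndsm)
}

#' Below-canopy prism volume
#'
#' The volume between the ground and the lowest part of the canopy is
#' modelled as a prism: footprint area times the canopy-to-ground
#' clearance \code{d}. \code{d} is either the orchard-mean clearance
#' (one value for all trees) or each tree's measured value.
#'
#' @param footprintArea projected crown area (m^2).
#' @param d canopy-to-ground clearance (m), >= 0.
#' @return volume in m^3.
#' @examples
#' belowCanopyVolume(7, 0.7) # 4.9
#' @export
belowCanopyVolume <- function(footprintArea, d) {
  if (any(d < 0)) stop("clearance d must be >= 0")
  footprintArea * d
}

#' Net canopy volume
#'
#' Total volume minus the below-canopy prism, clamped at zero: an
#' orchard-mean clearance can exceed a small tree's mean canopy height,
#' and a negative canopy volume is meaningless. Clamping is reported
#' with a warning.
#'
#' @param total,below volumes (m^3), both >= 0.
#' @return net volume in m^3.
#' @export
netCanopyVolume <- function(total, below) {
  stopifnot(all(total >= 0), all(below >= 0))
  net <- total - below
  if (any(net < 0)) {
    warning(sum(net < 0), " tree(s) with below-canopy volume exceeding ",
            "total volume; net volume clamped to 0")
    net <- pmax(net, 0)
  }
  net
}

#' Ellipsoid canopy volume (field method)
#'
#' The manual field method models the crown as an ellipsoid with
#' semi-axes D1/2, D2/2 and (Ht - Hb)/2:
#' \deqn{V = \frac{4\pi}{3}\,\frac{D_1}{2}\,\frac{D_2}{2}\,\frac{H_t - H_b}{2}}
#' with D1, D2 the crown diameters, Ht the tree height and Hb the lowest
#' canopy height above ground.
#'
#' @param d1,d2 crown diameters (m), > 0.
#' @param ht tree height (m).
#' @param hb lowest canopy height (m), < \code{ht}.
#' @return volume in m^3.
#' @examples
#' ellipsoidVolume(2, 2, 2.7, 0.7) # unit sphere: 4 * pi / 3
#' @export
ellipsoidVolume <- function(d1, d2, ht, hb) {
  if (any(d1 <= 0) || any(d2 <= 0)) stop("crown diameters must be > 0")
  if (any(ht <= hb)) stop("tree height must exceed the lowest canopy height")
  (4 * pi / 3) * (d1 / 2) * (d2 / 2) * ((ht - hb) / 2)
}

#' Trunk cross-sectional area from circumference
#'
#' Assumes a circular trunk: \code{TCSA = C^2 / (4 * pi)}, with the
#' circumference measured 0.40 m above ground.
#'
#' @param circumference trunk circumference (m), > 0.
#' @return area in m^2.
#' @export
tcsa <- function(circumference) {
  if (any(circumference <= 0)) stop("circumference must be > 0")
  circumference^2 / (4 * pi)
}

#' Per-tree trait table
#'
#' Computes height, equivalent-circle diameter, projected area and
#' gross/below/net canopy volumes for every segment, using either the
#' orchard-mean clearance (\code{d} scalar) or per-tree clearances
#' (\code{dTable}: tree_id, d, with segments matched to trees first).
#'
#' @param ndsm \linkS4class{RasterGrid} of heights above ground (m).
#' @param dsm,dtm aligned elevation grids (m) for the height estimate.
#' @param segments a \linkS4class{CrownSegmentSet}.
#' @param d orchard-mean canopy clearance (m); ignored when
#'   \code{dTable} is given.
#' @param dTable optional data.frame \code{tree_id}, \code{d} of per-tree
#'   clearances; requires \code{matching}.
#' @param matching result of \code{\link{matchSegmentsToTruth}} linking
#'   segment labels to tree_ids (needed with \code{dTable}).
#' @param ringWidth annulus width (m) for the terrain average.
#' @return data.frame: tree_id (NA when unmatched), label, height_m,
#'   diameter_m, projected_area_m2, total_volume_m3, below_volume_m3,
#'   net_volume_m3.
#' @export
treeMetrics <- function(ndsm, dsm, dtm, segments, d = 0.7, dTable = NULL,
                        matching = NULL, ringWidth = 2) {
  tab <- segmentTable(segments)
  if (!nrow(tab))
    return(data.frame(tree_id = character(0), label = integer(0),
                      height_m = numeric(0), diameter_m = numeric(0),
                      projected_area_m2 = numeric(0),
                      total_volume_m3 = numeric(0),
                      below_volume_m3 = numeric(0),
                      net_volume_m3 = numeric(0)))
  treeIds <- rep(NA_character_, nrow(tab))
  if (!is.null(matching)) {
    m <- match(tab$label, matching$pairs$label)
    treeIds <- as.character(matching$pairs$tree_id[m])
  }
  if (!is.null(dTable)) {
    if (is.null(matching))
      stop("per-tree clearances require a segment-to-tree matching")
    dm <- dTable$d[match(treeIds, dTable$tree_id)]
    missing <- treeIds[!is.na(treeIds) & is.na(dm)]
    if (length(missing))
      stop("no clearance d in dTable for tree(s): ",
           paste(missing, collapse = ", "))
    dvec <- dm
    dvec[is.na(dvec)] <- d # unmatched segments fall back to the mean
  } else {
    dvec <- rep(d, nrow(tab))
  }
  height <- vapply(tab$label, function(l)
    treeHeight(dsm, dtm, segments, l, ringWidth = ringWidth), numeric(1))
  total <- vapply(tab$label, function(l)
    totalVolume(ndsm, segments, l), numeric(1))
  below <- belowCanopyVolume(tab$footprint_area, dvec)
  data.frame(
    tree_id = treeIds,
    label = tab$label,
    height_m = height,
    diameter_m = crownDiameter(tab$footprint_area),
    projected_area_m2 = tab$footprint_area,
    total_volume_m3 = total,
    below_volume_m3 = below,
    net_volume_m3 = netCanopyVolume(total, below)
  )
}
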