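## Terrain reconstruction: DSM -> ground points -> TIN DTM -> nDSM.

#' Provisional canopy mask for ground-point sampling
#'
#' Flags pixels likely to belong to tree crowns before any segmentation
#' exists, so that ground points are only sampled between and within the
#' rows. A coarse background surface is formed from a low quantile of the
#' DSM within blocks of roughly one tree spacing; pixels more than
#' \code{heightThreshold} above that background are flagged and the mask
#' is dilated to protect crown edges.
#'
#' @param dsm \linkS4class{RasterGrid} of surface elevations (m).
#' @param heightThreshold height above background marking canopy (m).
#' @param blockSize background block size (m), about one tree spacing.
#' @param quantile background quantile within each block; soil must
#'   dominate each block for this to stay on the ground.
#' @param dilate dilation radius in pixels.
#' @return logical matrix aligned with \code{dsm} (TRUE = canopy).
#' @export
provisionalCanopyMask <- function(dsm, heightThreshold = 0.5, blockSize = 5,
                                  quantile = 0.3, dilate = 3L) {
  v <- gridValues(dsm)
  nr <- nrow(v); ncl <- ncol(v)
  bi <- pmax(1L, ceiling((seq_len(nr) * dsm@pixelSizeY) / blockSize))
  bj <- pmax(1L, ceiling((seq_len(ncl) * dsm@pixelSizeX) / blockSize))
  bg <- matrix(NA_real_, max(bi), max(bj))
  for (i in seq_len(max(bi))) {
    rows <- which(bi == i)
    for (j in seq_len(max(bj))) {
      cells <- v[rows, which(bj == j)]
      cells <- cells[!is.na(cells)]
      if (length(cells))
        bg[i, j] <- stats::quantile(cells, quantile, names = FALSE, type = 1)
    }
  }
  mask <- !is.na(v) & (v - bg[cbind(bi[row(v)], bj[col(v)])]) > heightThreshold
  if (dilate > 0L) mask <- .dilateMask(mask, dilate)
  mask
}

# square structuring-element binary dilation via an integral image
.dilateMask <- function(mask, radius) {
  nr <- nrow(mask); ncl <- ncol(mask)
  m <- matrix(0, nr + 2L * radius, ncl + 2L * radius)
  m[radius + seq_len(nr), radius + seq_len(ncl)] <- mask
  ii <- apply(m, 2L, cumsum)
  ii <- t(apply(ii, 1L, cumsum)) # ii[i, j] = sum over m[1:i, 1:j]
  P <- matrix(0, nrow(m) + 1L, ncol(m) + 1L)
  P[-1L, -1L] <- ii
  a <- seq_len(nr); b <- a + 2L * radius       # padded row window a..b
  cA <- seq_len(ncl); cB <- cA + 2L * radius   # padded col window
  total <- P[b + 1L, cB + 1L] - P[a, cB + 1L] - P[b + 1L, cA] + P[a, cA]
  total > 0
}

#' Sample ground points from a DSM
#'
#' Collects bare-ground elevation samples on a regular grid across the
#' scene, skipping canopy pixels, as the support for DTM interpolation.
#' Within each sampling cell the sample is the pixel attaining a low
#' quantile of the non-masked elevations (robust against stray
#' vegetation), located at that pixel's centre.
#'
#' @param dsm \linkS4class{RasterGrid} of surface elevations (m).
#' @param exclusionMask logical matrix aligned with \code{dsm}; TRUE
#'   pixels (canopy) are never sampled. \code{NULL} = no exclusion.
#' @param gridStep sampling cell size (m); half the tree spacing works
#'   well for regular orchards.
#' @param quantile elevation quantile taken within each sampling cell.
#' @return data.frame with columns \code{x}, \code{y}, \code{z} (m).
#' @seealso [buildDtm()], [provisionalCanopyMask()]
#' @export
sampleGroundPoints <- function(dsm, exclusionMask = NULL, gridStep = 2.5,
                               quantile = 0.1) {
  v <- gridValues(dsm)
  if (is.null(exclusionMask)) exclusionMask <- matrix(FALSE, nrow(v), ncol(v))
  if (!all(dim(exclusionMask) == dim(v)))
    stop("exclusionMask is not aligned with the DSM")
  cc <- cellCoordinates(dsm)
  usable <- !exclusionMask & !is.na(v)
  bi <- pmax(1L, ceiling((nrow(v):1 * dsm@pixelSizeY) / gridStep)) # south-up blocks
  bj <- pmax(1L, ceiling((seq_len(ncol(v)) * dsm@pixelSizeX) / gridStep))
  pts <- list()
  for (i in unique(bi)) {
    rows <- which(bi == i)
    for (j in unique(bj)) {
      cols <- which(bj == j)
      sub <- usable[rows, cols, drop = FALSE]
      if (!any(sub)) next
      zz <- v[rows, cols, drop = FALSE][sub]
      zq <- stats::quantile(zz, quantile, names = FALSE, type = 1)
      hit <- which(sub & v[rows, cols, drop = FALSE] == zq,
                   arr.ind = TRUE)[1L, ]
      pts[[length(pts) + 1L]] <- c(cc$x[cols[hit[2L]]], cc$y[rows[hit[1L]]], zq)
    }
  }
  if (length(pts) < 3L)
    stop("fewer than 3 usable ground points; check the exclusion mask")
  out <- as.data.frame(do.call(rbind, pts))
  names(out) <- c("x", "y", "z")
  out
}

#' Interpolate a DTM from ground points
#'
#' Delaunay-triangulates the ground samples and rasterizes the resulting
#' piecewise-linear surface (TIN) on the template grid; cells outside the
#' convex hull of the samples take the elevation of the nearest sample.
#' Linear interpolation reproduces any planar terrain exactly.
#'
#' @param points data.frame with columns \code{x}, \code{y}, \code{z}
#'   (m), at least 3 non-collinear rows.
#' @param template \linkS4class{RasterGrid} defining the output grid.
#' @return a \linkS4class{RasterGrid} of bare-ground elevations.
#' @export
buildDtm <- function(points, template) {
  stopifnot(all(c("x", "y", "z") %in% names(points)))
  v <- .tinInterpolate(points$x, points$y, points$z, template)
  withValues(template, v, units = "m")
}

#' Normalized surface model (canopy height model)
#'
#' Subtracts the terrain from the surface model; negative differences
#' (interpolation noise) are clamped to zero, since heights below ground
#' are physically meaningless and would corrupt volume sums. Nodata in
#' either input propagates.
#'
#' @param dsm,dtm aligned \linkS4class{RasterGrid}s (m).
#' @return a \linkS4class{RasterGrid} of heights above ground (m).
#' @export
computeNdsm <- function(dsm, dtm) {
  .checkAligned(dsm, dtm, "DSM and DTM")
  v <- pmax(gridValues(dsm) - gridValues(dtm), 0)
  withValues(dsm, v, units = "m")
}

#' One-call DTM derivation from a DSM
#'
#' Convenience wrapper chaining \code{\link{provisionalCanopyMask}},
#' \code{\link{sampleGroundPoints}} and \code{\link{buildDtm}}.
#'
#' @inheritParams sampleGroundPoints
#' @inheritParams provisionalCanopyMask
#' @return a \linkS4class{RasterGrid}.
#' @export
deriveDtm <- function(dsm, gridStep = 2.5, heightThreshold = 0.5,
                      blockSize = 5) {
  mask <- provisionalCanopyMask(dsm, heightThreshold = heightThreshold,
                                blockSize = blockSize)
  pts <- sampleGroundPoints(dsm, mask, gridStep = gridStep)
  buildDtm(pts, dsm)
}
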