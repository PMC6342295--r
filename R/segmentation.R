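## Individual crown delineation on the nDSM: local adaptive thresholding
## (Niblack / Sauvola) + 8-connected component labelling. No watershed is
## used: at regular orchard spacing crowns do not overlap.

.boxStats <- function(v, radius) {
  ok <- !is.na(v)
  v0 <- ifelse(ok, v, 0)
  boxsum <- function(m) {
    nr <- nrow(m); ncl <- ncol(m)
    p <- matrix(0, nr + 2L * radius, ncl + 2L * radius)
    p[radius + seq_len(nr), radius + seq_len(ncl)] <- m
    ii <- apply(p, 2L, cumsum)
    ii <- t(apply(ii, 1L, cumsum))
    P <- matrix(0, nrow(p) + 1L, ncol(p) + 1L)
    P[-1L, -1L] <- ii
    a <- seq_len(nr); b <- a + 2L * radius
    cA <- seq_len(ncl); cB <- cA + 2L * radius
    P[b + 1L, cB + 1L] - P[a, cB + 1L] - P[b + 1L, cA] + P[a, cA]
  }
  n <- boxsum(ok * 1)
  s1 <- boxsum(v0)
  s2 <- boxsum(v0^2)
  mean <- ifelse(n > 0, s1 / n, 0)
  varr <- pmax(ifelse(n > 0, s2 / n - mean^2, 0), 0)
  list(mean = mean, sd = sqrt(varr), n = n)
}

#' Parameters for crown segmentation
#'
#' @slot method "niblack", "sauvola" or "fixed".
#' @slot window local window side in pixels (odd, >= 3); \code{NA} lets
#'   \code{\link{localThreshold}} pick about 1.5 expected crown diameters
#'   (assumed 3 m) at the grid's resolution.
#' @slot k thresholding sensitivity: Niblack default -0.2, Sauvola 0.5.
#' @slot r Sauvola dynamic-range normalizer; \code{NA} = half the value
#'   range of the thresholded grid.
#' @slot heightThreshold fixed-method cut (m above ground).
#' @slot minArea smallest crown footprint kept (m^2).
#' @export
setClass("SegmentationParams",
  representation(method = "character", window = "integer", k = "numeric",
                 r = "numeric", heightThreshold = "numeric",
                 minArea = "numeric"),
  prototype(method = "sauvola", window = NA_integer_, k = NA_real_,
            r = NA_real_, heightThreshold = 0.5, minArea = 0.5)
)

setValidity("SegmentationParams", function(object) {
  if (!object@method %in% c("niblack", "sauvola", "fixed"))
    return("method must be one of niblack, sauvola, fixed")
  if (!is.na(object@window) &&
      (object@window < 3L || object@window %% 2L == 0L))
    return("window must be odd and >= 3")
  if (object@minArea <= 0) return("minArea must be > 0")
  TRUE
})

#' @rdname SegmentationParams-class
#' @param method,window,k,r,heightThreshold,minArea see slots.
#' @export
segmentationParams <- function(method = "sauvola", window = NA, k = NA,
                               r = NA, heightThreshold = 0.5,
                               minArea = 0.5) {
  p <- new("SegmentationParams", method = method,
           window = as.integer(window), k = as.numeric(k),
           r = as.numeric(r), heightThreshold = heightThreshold,
           minArea = minArea)
  validObject(p)
  p
}

.defaultK <- function(method) switch(method, niblack = -0.2, sauvola = 0.5, 0)

#' Local adaptive thresholding of a height raster
#'
#' Separates crown pixels from background on the nDSM. Niblack classifies
#' a pixel as crown when its value exceeds the local window mean plus
#' \code{k} local standard deviations; Sauvola when it exceeds
#' \code{m * (1 + k * (s / r - 1))}; the fixed method applies one global
#' height cut. A pixel exactly at its threshold is background, which
#' keeps constant images (local sd 0) all-background. Nodata pixels are
#' background. Window statistics at the grid border use the clipped
#' window.
#'
#' For the adaptive methods \code{heightThreshold} additionally acts as
#' the soil/tree delimitation: over bare soil the local statistics of an
#' nDSM are near zero and the adaptive rules alone would promote any
#' positive interpolation residue to crown, so a pixel must also exceed
#' \code{heightThreshold} metres above ground. Set it to \code{-Inf} for
#' the pure Niblack/Sauvola decision.
#'
#' @param grid \linkS4class{RasterGrid}, typically an nDSM in metres.
#' @param params a \linkS4class{SegmentationParams}.
#' @return logical matrix aligned with \code{grid} (TRUE = crown).
#' @examples
#' nd <- rasterGrid(matrix(c(rep(0, 40), rep(3, 9), rep(0, 32)), 9),
#'                  pixelSize = 1)
#' table(localThreshold(nd, segmentationParams("fixed", heightThreshold = 0.5)))
#' @export
localThreshold <- function(grid, params = segmentationParams()) {
  stopifnot(is(grid, "RasterGrid"))
  validObject(params)
  v <- gridValues(grid)
  if (params@method == "fixed") {
    mask <- !is.na(v) & v > params@heightThreshold
    return(mask)
  }
  window <- params@window
  if (is.na(window)) {
    window <- as.integer(round(1.5 * 3 / grid@pixelSizeX))
    window <- max(3L, window + (1L - window %% 2L))
  }
  if (window > max(dim(v)) * 2L - 1L)
    stop("window (", window, " px) larger than the grid")
  radius <- (window - 1L) %/% 2L
  st <- .boxStats(v, radius)
  k <- if (is.na(params@k)) .defaultK(params@method) else params@k
  if (params@method == "niblack") {
    thr <- st$mean + k * st$sd
  } else {
    r <- params@r
    if (is.na(r)) {
      rng <- range(v, na.rm = TRUE)
      r <- (rng[2] - rng[1]) / 2
      if (r <= 0) r <- 1
    }
    thr <- st$mean * (1 + k * (st$sd / r - 1))
  }
  !is.na(v) & v > thr & v > params@heightThreshold
}

#' Label connected crown components
#'
#' 8-connected component labelling of a binary crown mask, dropping
#' components smaller than \code{minArea}. Labels are assigned in
#' raster-scan (row-major) order of each component's first pixel.
#'
#' @param mask logical matrix (TRUE = crown).
#' @param template \linkS4class{RasterGrid} the mask is aligned with
#'   (supplies pixel size and world coordinates).
#' @param minArea smallest footprint kept, m^2.
#' @return a \linkS4class{CrownSegmentSet}.
#' @export
labelCrowns <- function(mask, template, minArea = 0.5) {
  stopifnot(is.logical(mask), all(dim(mask) == dim(template)))
  nr <- nrow(mask); ncl <- ncol(mask)
  lab <- matrix(0L, nr, ncl)
  parent <- integer(0)
  findRoot <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  nlab <- 0L
  for (i in seq_len(nr)) {
    r <- rle(mask[i, ])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      s <- starts[k]; e <- ends[k]
      if (i > 1L) {
        above <- lab[i - 1L, max(s - 1L, 1L):min(e + 1L, ncl)]
        nb <- unique(above[above > 0L])
      } else nb <- integer(0)
      if (!length(nb)) {
        nlab <- nlab + 1L
        parent[nlab] <- nlab
        lab[i, s:e] <- nlab
      } else {
        roots <- unique(vapply(nb, findRoot, integer(1)))
        tgt <- min(roots)
        for (rt in roots) parent[rt] <- tgt
        lab[i, s:e] <- tgt
      }
    }
  }
  if (nlab > 0L) {
    rootOf <- vapply(seq_len(nlab), findRoot, integer(1))
    lab[lab > 0L] <- rootOf[lab[lab > 0L]]
  }
  pa <- pixelArea(template)
  cc <- cellCoordinates(template)
  idx <- which(lab > 0L)
  out <- withValues(template, matrix(NA_real_, nr, ncl), units = "label")
  if (!length(idx)) {
    return(new("CrownSegmentSet",
               labels = withValues(template, matrix(0, nr, ncl), units = "label"),
               table = data.frame(label = integer(0), n_pixels = integer(0),
                                  footprint_area = numeric(0),
                                  centroid_x = numeric(0), centroid_y = numeric(0),
                                  row_min = integer(0), row_max = integer(0),
                                  col_min = integer(0), col_max = integer(0))))
  }
  ri <- (idx - 1L) %% nr + 1L
  ci <- (idx - 1L) %/% nr + 1L
  comp <- lab[idx]
  # raster-scan order of each component's first pixel
  scanPos <- (ri - 1L) * ncl + ci
  firstPos <- tapply(scanPos, comp, min)
  ord <- names(sort(firstPos))
  newId <- stats::setNames(seq_along(ord), ord)
  comp <- as.integer(newId[as.character(comp)])
  npix <- tabulate(comp)
  keep <- which(npix * pa >= minArea)
  remap <- integer(length(npix))
  remap[keep] <- seq_along(keep)
  comp2 <- remap[comp]
  sel <- comp2 > 0L
  labOut <- matrix(0, nr, ncl)
  labOut[idx[sel]] <- comp2[sel]
  if (!length(keep)) {
    tab <- data.frame(label = integer(0), n_pixels = integer(0),
                      footprint_area = numeric(0), centroid_x = numeric(0),
                      centroid_y = numeric(0), row_min = integer(0),
                      row_max = integer(0), col_min = integer(0),
                      col_max = integer(0))
  } else {
    g <- comp2[sel]
    xw <- cc$x[ci[sel]]; yw <- cc$y[ri[sel]]
    tab <- data.frame(
      label = seq_along(keep),
      n_pixels = as.integer(tabulate(g, length(keep))),
      footprint_area = tabulate(g, length(keep)) * pa,
      centroid_x = as.numeric(tapply(xw, g, mean)),
      centroid_y = as.numeric(tapply(yw, g, mean)),
      row_min = as.integer(tapply(ri[sel], g, min)),
      row_max = as.integer(tapply(ri[sel], g, max)),
      col_min = as.integer(tapply(ci[sel], g, min)),
      col_max = as.integer(tapply(ci[sel], g, max))
    )
  }
  new("CrownSegmentSet",
      labels = withValues(template, labOut, units = "label"),
      table = tab)
}

#' Accessors for CrownSegmentSet
#'
#' \code{segmentTable} returns the per-segment data.frame;
#' \code{labelRaster} the integer label \linkS4class{RasterGrid}
#' (0 = background); \code{segmentMask} the logical pixel mask of one
#' segment; \code{length} the number of segments.
#'
#' @param x a \linkS4class{CrownSegmentSet}.
#' @param label a segment label present in \code{segmentTable(x)$label}.
#' @name CrownSegmentSet-accessors
#' @aliases segmentTable labelRaster segmentMask
NULL

#' @rdname CrownSegmentSet-accessors
#' @export
setMethod("segmentTable", "CrownSegmentSet", function(x) x@table)

#' @rdname CrownSegmentSet-accessors
#' @export
setMethod("labelRaster", "CrownSegmentSet", function(x) x@labels)

#' @rdname CrownSegmentSet-accessors
#' @export
setMethod("segmentMask", "CrownSegmentSet", function(x, label) {
  gridValues(x@labels) == label
})

#' @export
setMethod("length", "CrownSegmentSet", function(x) nrow(x@table))

setMethod("show", "CrownSegmentSet", function(object) {
  cat("CrownSegmentSet:", nrow(object@table), "segments\n")
  if (nrow(object@table)) {
    cat("  footprint area (m^2): [",
        signif(min(object@table$footprint_area), 4), ",",
        signif(max(object@table$footprint_area), 4), "]\n")
  }
})

#' Match segments to a per-tree truth or field table
#'
#' One-to-one greedy nearest-centroid pairing between delineated segments
#' and known tree positions, within \code{maxDist}. Candidate pairs are
#' taken in order of increasing distance; exact ties are resolved by
#' segment label order, so the pairing is deterministic.
#'
#' @param segments a \linkS4class{CrownSegmentSet}.
#' @param trees data.frame with columns \code{tree_id}, \code{x}, \code{y}.
#' @param maxDist largest centre-to-centroid distance allowed (m).
#' @return list with \code{pairs} (data.frame: tree_id, label, dist),
#'   \code{unmatchedTrees} (tree_id), \code{unmatchedSegments} (labels).
#' @export
matchSegmentsToTruth <- function(segments, trees, maxDist = 2.5) {
  tab <- segmentTable(segments)
  if (!nrow(tab) || !nrow(trees)) {
    return(list(pairs = data.frame(tree_id = character(0), label = integer(0),
                                   dist = numeric(0)),
                unmatchedTrees = trees$tree_id,
                unmatchedSegments = tab$label))
  }
  d <- outer(trees$x, tab$centroid_x, "-")^2 +
       outer(trees$y, tab$centroid_y, "-")^2
  d <- sqrt(d)
  cand <- which(d <= maxDist, arr.ind = TRUE)
  ord <- order(d[cand], cand[, 2]) # distance, then label order on ties
  cand <- cand[ord, , drop = FALSE]
  usedT <- logical(nrow(trees)); usedS <- logical(nrow(tab))
  pairs <- list()
  for (k in seq_len(nrow(cand))) {
    ti <- cand[k, 1]; si <- cand[k, 2]
    if (usedT[ti] || usedS[si]) next
    usedT[ti] <- TRUE; usedS[si] <- TRUE
    pairs[[length(pairs) + 1L]] <-
      data.frame(tree_id = trees$tree_id[ti], label = tab$label[si],
                 dist = d[ti, si])
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(tree_id = character(0), label = integer(0), dist = numeric(0))
  list(pairs = pairs,
       unmatchedTrees = trees$tree_id[!usedT],
       unmatchedSegments = tab$label[!usedS])
}
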