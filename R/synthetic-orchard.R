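## Synthetic orchard scenes with analytic ground truth.
##
## Crowns are solid ellipsoids on their truth parameters: a nadir camera
## sees the upper half-surface, so over a crown footprint the surface is
##   z_top(x, y) = terrain + Hb + c + c * sqrt(1 - (dx/a)^2 - (dy/b)^2)
## with a = D1/2, b = D2/2, c = (Ht - Hb)/2. Two closed forms anchor all
## volume tests: the ellipsoid (field) volume (4/3) pi a b c, and the
## surface integral over the footprint of (z_top - ground - Hb),
##   integral (c + c sqrt(1 - r^2)) dA = pi a b c + (2/3) pi a b c
##                                     = (5/3) pi a b c,
## i.e. exactly 5/4 of the ellipsoid volume. An optional central
## depression (the open "vase" core of trained olive canopies) removes
##   hcf * [ pi a b c rc^2 + (2/3) pi a b c (1 - (1 - rc^2)^(3/2)) ]
## from that integral (hcf = depth fraction, rc = core radius fraction).

.runWithSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

.subSeeds <- function(seed, n) {
  .runWithSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Scene configuration for the synthetic orchard generator
#'
#' Defaults emulate an intensive olive orchard: trees on a regular
#' 5 x 5 m grid (three rows of five trees), ground sample distance
#' 0.02 m, tree heights 2.1-3.9 m, crown diameters 2.0-3.8 m, lowest
#' canopy height (ground clearance) about 0.7 m, crown NDVI increasing
#' with leaf area index from about 0.30 to 0.70 over bare soil at about
#' 0.10, and gently varying terrain (1 % gradient plus a smooth 0.1 m
#' amplitude undulation at 20-50 m wavelengths).
#'
#' @slot treeRows,treeCols number of tree rows and trees per row.
#' @slot spacingX,spacingY planting distances (m).
#' @slot gsd ground sample distance (m).
#' @slot buffer bare-soil margin around the planted block (m).
#' @slot baseElevation terrain elevation at the grid origin (m).
#' @slot gradientX,gradientY terrain plane gradient (m/m).
#' @slot noiseAmplitude peak amplitude of the smooth terrain
#'   undulation (m); 0 gives an exact plane.
#' @slot wavelengthRange wavelengths (m) of the terrain undulation.
#' @slot d1Range,d2Range crown diameter ranges (m); must stay below the
#'   planting distances so crowns cannot overlap.
#' @slot htRange tree height range (m).
#' @slot hbMean,hbSd lowest-canopy-height distribution (m).
#' @slot hollowCoreFraction depth fraction of the central vase
#'   depression, in [0, 1); 0 = solid ellipsoid crowns.
#' @slot coreRadiusFraction radius of the vase core as a fraction of the
#'   crown semi-axes, in (0, 1).
#' @slot laiRange leaf area index range across trees.
#' @slot ndviNoiseSd per-pixel reflectance noise, as NDVI standard
#'   deviation.
#' @slot soilNdvi NDVI of bare soil.
#' @export
setClass("SceneConfig",
  representation(
    treeRows = "integer", treeCols = "integer",
    spacingX = "numeric", spacingY = "numeric",
    gsd = "numeric", buffer = "numeric",
    baseElevation = "numeric", gradientX = "numeric", gradientY = "numeric",
    noiseAmplitude = "numeric", wavelengthRange = "numeric",
    d1Range = "numeric", d2Range = "numeric", htRange = "numeric",
    hbMean = "numeric", hbSd = "numeric",
    hollowCoreFraction = "numeric", coreRadiusFraction = "numeric",
    laiRange = "numeric", ndviNoiseSd = "numeric", soilNdvi = "numeric"
  ),
  prototype(
    treeRows = 3L, treeCols = 5L, spacingX = 5, spacingY = 5,
    gsd = 0.02, buffer = 2.5,
    baseElevation = 100, gradientX = 0.01, gradientY = 0.01,
    noiseAmplitude = 0.10, wavelengthRange = c(20, 50),
    d1Range = c(2.0, 3.8), d2Range = c(2.0, 3.8), htRange = c(2.1, 3.9),
    hbMean = 0.7, hbSd = 0.05,
    hollowCoreFraction = 0, coreRadiusFraction = 0.4,
    laiRange = c(1.0, 3.5), ndviNoiseSd = 0.02, soilNdvi = 0.10
  )
)

setValidity("SceneConfig", function(object) {
  msg <- character()
  if (object@gsd <= 0) msg <- c(msg, "gsd must be > 0")
  if (object@treeRows < 1L || object@treeCols < 1L)
    msg <- c(msg, "need at least one tree")
  maxD <- max(object@d1Range, object@d2Range)
  if (maxD >= min(object@spacingX, object@spacingY))
    msg <- c(msg, sprintf(
      "crowns could overlap: max crown diameter %.2f m >= tree spacing %.2f m",
      maxD, min(object@spacingX, object@spacingY)))
  if (object@hollowCoreFraction < 0 || object@hollowCoreFraction >= 1)
    msg <- c(msg, "hollowCoreFraction must be in [0, 1)")
  if (diff(object@htRange) < 0 || min(object@htRange) <= object@hbMean)
    msg <- c(msg, "tree heights must exceed the lowest canopy height")
  if (length(msg)) msg else TRUE
})

#' @rdname SceneConfig-class
#' @param ... slot values overriding the defaults (see slots above).
#' @return a validated \linkS4class{SceneConfig}.
#' @examples
#' cfg <- sceneConfig(treeRows = 1L, treeCols = 1L, noiseAmplitude = 0)
#' @export
sceneConfig <- function(...) {
  args <- list(...)
  for (nm in c("treeRows", "treeCols"))
    if (nm %in% names(args)) args[[nm]] <- as.integer(args[[nm]])
  obj <- do.call(new, c(list("SceneConfig"), args))
  validObject(obj)
  obj
}

.terrainField <- function(config, xs, ys, seed) {
  base <- outer(ys * config@gradientY, xs * config@gradientX, "+") +
    config@baseElevation
  if (config@noiseAmplitude > 0) {
    .runWithSeed(seed, {
      k <- 4L
      theta <- runif(k, 0, 2 * pi)
      lambda <- runif(k, config@wavelengthRange[1], config@wavelengthRange[2])
      phase <- runif(k, 0, 2 * pi)
      w <- rep(1 / k, k)
      for (i in seq_len(k)) {
        proj <- outer(ys * sin(theta[i]), xs * cos(theta[i]), "+")
        base <- base + config@noiseAmplitude * w[i] *
          cos(2 * pi * proj / lambda[i] + phase[i])
      }
    })
  }
  base
}

.drawTrees <- function(config, seed) {
  n <- config@treeRows * config@treeCols
  .runWithSeed(seed, {
    idx <- expand.grid(col = seq_len(config@treeCols),
                       row = seq_len(config@treeRows))
    d1 <- runif(n, config@d1Range[1], config@d1Range[2])
    d2 <- runif(n, config@d2Range[1], config@d2Range[2])
    ht <- runif(n, config@htRange[1], config@htRange[2])
    hb <- pmin(pmax(rnorm(n, config@hbMean, config@hbSd), 0.3), ht - 0.5)
    lai <- runif(n, config@laiRange[1], config@laiRange[2])
    laiMax <- config@laiRange[2]
    spad <- 30 + 25 * lai / laiMax + rnorm(n, 0, 1)
    a <- d1 / 2; b <- d2 / 2; cc <- (ht - hb) / 2
    ell <- (4 * pi / 3) * a * b * cc
    rc <- config@coreRadiusFraction
    hcf <- config@hollowCoreFraction
    deficit <- hcf * (pi * a * b * cc * rc^2 +
                      (2 / 3) * pi * a * b * cc * (1 - (1 - rc^2)^1.5))
    data.frame(
      tree_id = sprintf("T%02d", seq_len(n)),
      x = config@buffer + (idx$col - 0.5) * config@spacingX,
      y = config@buffer + (idx$row - 0.5) * config@spacingY,
      d1 = d1, d2 = d2, ht = ht, hb = hb, d = hb,
      ellipsoid_volume = ell,
      surface_integral_volume = (5 / 3) * pi * a * b * cc - deficit,
      lai_true = lai, spad_true = spad,
      ndvi_true = 0.30 + 0.40 * lai / laiMax
    )
  })
}

#' Generate a synthetic orchard scene
#'
#' Builds the four rasters a UAV campaign over the orchard would deliver
#' (DSM, true DTM, NIR and RED reflectance) together with the per-tree
#' analytic truth table. The same seed always reproduces the identical
#' scene bit for bit.
#'
#' @param config a \linkS4class{SceneConfig}.
#' @param seed integer master seed; per-raster sub-seeds are derived
#'   from it.
#' @return a list with elements \code{dsm}, \code{dtm_true}, \code{nir},
#'   \code{red} (each a \linkS4class{RasterGrid}) and \code{trees}
#'   (data.frame: tree_id, x, y, d1, d2, ht, hb, d, ellipsoid_volume,
#'   surface_integral_volume, lai_true, spad_true, ndvi_true).
#' @examples
#' sc <- generateScene(sceneConfig(gsd = 0.05), seed = 1)
#' nrow(sc$trees)
#' @export
generateScene <- function(config = sceneConfig(), seed = 1L) {
  validObject(config)
  seeds <- .subSeeds(seed, 3L)
  width <- config@treeCols * config@spacingX + 2 * config@buffer
  height <- config@treeRows * config@spacingY + 2 * config@buffer
  ncols <- max(1L, round(width / config@gsd))
  nrows <- max(1L, round(height / config@gsd))
  xs <- (seq_len(ncols) - 0.5) * config@gsd
  ys <- (nrows - seq_len(nrows) + 0.5) * config@gsd # row 1 = north
  terrain <- .terrainField(config, xs, ys, seeds[1L])
  trees <- .drawTrees(config, seeds[2L])

  dsm <- terrain
  crownMask <- matrix(FALSE, nrows, ncols)
  crownNdvi <- matrix(NA_real_, nrows, ncols)
  hcf <- config@hollowCoreFraction
  rc <- config@coreRadiusFraction
  for (i in seq_len(nrow(trees))) {
    a <- trees$d1[i] / 2; b <- trees$d2[i] / 2
    cc <- (trees$ht[i] - trees$hb[i]) / 2
    jj <- which(abs(xs - trees$x[i]) <= a)
    ii <- which(abs(ys - trees$y[i]) <= b)
    if (!length(jj) || !length(ii)) next
    u <- (xs[jj] - trees$x[i]) / a
    v <- (ys[ii] - trees$y[i]) / b
    r2 <- outer(v^2, u^2, "+")
    inside <- r2 <= 1
    if (!any(inside)) next
    rel <- cc * (1 + sqrt(pmax(1 - r2, 0)))
    if (hcf > 0) {
      core <- inside & r2 < rc^2
      rel[core] <- (1 - hcf) * rel[core]
    }
    sub <- dsm[ii, jj, drop = FALSE]
    top <- sub + trees$hb[i] + rel
    sub[inside] <- top[inside]
    dsm[ii, jj] <- sub
    m <- crownMask[ii, jj, drop = FALSE]; m[inside] <- TRUE
    crownMask[ii, jj] <- m
    nv <- crownNdvi[ii, jj, drop = FALSE]
    nv[inside] <- trees$ndvi_true[i]
    crownNdvi[ii, jj] <- nv
  }

  ndvi <- matrix(config@soilNdvi, nrows, ncols)
  ndvi[crownMask] <- crownNdvi[crownMask]
  if (config@ndviNoiseSd > 0) {
    .runWithSeed(seeds[3L], {
      ndvi <- ndvi + matrix(rnorm(nrows * ncols, 0, config@ndviNoiseSd),
                            nrows, ncols)
    })
  }
  ndvi <- pmin(pmax(ndvi, -0.99), 0.99)
  # back-solve band reflectances under a fixed NIR + RED = 0.6 albedo
  nir <- 0.3 * (1 + ndvi)
  red <- 0.3 * (1 - ndvi)

  mk <- function(v, units) {
    rasterGrid(v, xmin = 0, ymax = height, pixelSize = config@gsd,
               units = units, crs = "local-metric")
  }
  list(dsm = mk(dsm, "m"), dtm_true = mk(terrain, "m"),
       nir = mk(nir, "reflectance"), red = mk(red, "reflectance"),
       trees = trees)
}

#' Generate a seasonal stem water potential series
#'
#' Emulates the seasonal course of midday stem water potential over an
#' irrigation season: irrigated trees fluctuate around -1.8 MPa and stay
#' above -2.2 MPa, while rainfed trees decline from about -1.5 MPa toward
#' -4.5 MPa late in the season with a small rain-driven recovery around
#' DOY 228 and a relief recovery after DOY 273.
#'
#' @param regime "irrigated" or "rainfed".
#' @param doyGrid increasing integer days of year (default: every 7 days
#'   across the DOY 182-273 irrigation window).
#' @param seed integer seed.
#' @param noiseSd measurement noise (MPa); 0 gives a deterministic series.
#' @param treeId identifier stored on the series.
#' @return an \linkS4class{SWPSeries}.
#' @examples
#' s <- generateSwpSeries("rainfed", seed = 3)
#' min(swp(s))
#' @export
generateSwpSeries <- function(regime = c("irrigated", "rainfed"),
                              doyGrid = seq(182L, 273L, by = 7L),
                              seed = 1L, noiseSd = 0.08,
                              treeId = regime) {
  regime <- match.arg(regime)
  if (!length(doyGrid)) stop("doyGrid must be non-empty")
  doyGrid <- as.integer(doyGrid)
  if (length(doyGrid) > 1L && any(diff(doyGrid) <= 0L))
    stop("doyGrid must be strictly increasing")
  t <- doyGrid
  if (regime == "irrigated") {
    base <- -1.8 + 0.25 * sin(2 * pi * (t - 182) / 60)
  } else {
    frac <- pmin(pmax((t - 182) / (267 - 182), 0), 1)
    base <- -1.5 - 3.0 * frac^1.5
    base <- base + 0.6 * exp(-((t - 228) / 6)^2)   # rainfall relief
    base <- ifelse(t > 273, pmin(base + 1.5, -1.8), base) # relief irrigation
  }
  noise <- if (noiseSd > 0)
    .runWithSeed(seed, rnorm(length(t), 0, noiseSd)) else 0
  sw <- base + noise
  lim <- if (regime == "irrigated") c(-2.2, -1.4) else c(-4.6, -1.2)
  sw <- pmin(pmax(sw, lim[1]), lim[2])
  swpSeries(treeId = treeId[[1L]], doy = t, swp = sw)
}
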