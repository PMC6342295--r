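# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# Default 3 x 5-tree orchard scene (seed fixed arbitrarily) analysed end
# to end with the default pipeline components.
defaultAnalysis <- function() {
  if (!exists("default", .fixtures)) {
    scene <- generateScene(sceneConfig(), seed = 42)
    dtm <- deriveDtm(scene$dsm)
    ndsm <- computeNdsm(scene$dsm, dtm)
    segs <- labelCrowns(localThreshold(ndsm, segmentationParams()), ndsm)
    matching <- matchSegmentsToTruth(segs, scene$trees)
    metrics <- treeMetrics(ndsm, scene$dsm, dtm, segs,
                           dTable = scene$trees[, c("tree_id", "d")],
                           matching = matching)
    merged <- merge(metrics, scene$trees, by = "tree_id")
    assign("default", list(scene = scene, dtm = dtm, ndsm = ndsm,
                           segs = segs, matching = matching,
                           metrics = metrics, merged = merged), .fixtures)
  }
  get("default", .fixtures)
}

# Single canonical crown (D1 = 3, D2 = 2, Ht = 3.4, Hb = 0.7) on flat
# terrain: the configuration used for volume-convergence checks.
canonicalCrownScene <- function(gsd) {
  cfg <- sceneConfig(treeRows = 1L, treeCols = 1L, gsd = gsd,
                     d1Range = c(3, 3), d2Range = c(2, 2),
                     htRange = c(3.4, 3.4), hbMean = 0.7, hbSd = 0,
                     noiseAmplitude = 0, gradientX = 0, gradientY = 0,
                     ndviNoiseSd = 0)
  generateScene(cfg, seed = 1)
}

# Net canopy volume of the single crown in a noise-free scene, using the
# fixed-threshold footprint and the true DTM.
netVolumeOfScene <- function(scene) {
  ndsm <- computeNdsm(scene$dsm, scene$dtm_true)
  segs <- labelCrowns(
    localThreshold(ndsm, segmentationParams("fixed", heightThreshold = 0.5)),
    ndsm)
  stopifnot(length(segs) == 1L)
  totalVolume(ndsm, segs, 1) -
    segmentTable(segs)$footprint_area * scene$trees$hb
}

# Independent per-pixel oracle for the local thresholding decisions:
# naive double loop, clipped window, population mean/sd, strict >.
bruteForceThreshold <- function(v, method, window, k, r = NULL,
                                minHeight = -Inf) {
  nr <- nrow(v); ncl <- ncol(v)
  rad <- (window - 1L) %/% 2L
  out <- matrix(FALSE, nr, ncl)
  for (i in seq_len(nr)) {
    for (j in seq_len(ncl)) {
      if (is.na(v[i, j])) next
      win <- v[max(1L, i - rad):min(nr, i + rad),
               max(1L, j - rad):min(ncl, j + rad)]
      win <- win[!is.na(win)]
      m <- mean(win)
      s <- sqrt(mean(win^2) - m^2)
      thr <- if (method == "niblack") m + k * s
             else m * (1 + k * (s / r - 1))
      out[i, j] <- v[i, j] > thr && v[i, j] > minHeight
    }
  }
  out
}
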