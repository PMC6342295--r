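test_that("tree height is apex minus surrounding terrain", {
  # flat terrain at 100 m, a block crown with apex 103.2
  v <- matrix(100, 30, 30)
  v[14:17, 14:17] <- 103.2
  dsm <- rasterGrid(v, pixelSize = 0.5, units = "m")
  dtm <- rasterGrid(matrix(100, 30, 30), pixelSize = 0.5, units = "m")
  ndsm <- computeNdsm(dsm, dtm)
  segs <- labelCrowns(localThreshold(ndsm, segmentationParams(
    "fixed", heightThreshold = 0.5)), ndsm)
  expect_equal(treeHeight(dsm, dtm, segs, 1, ringWidth = 2), 3.2)
})

test_that("height on sloped terrain matches apex minus centre terrain", {
  # symmetric annulus on a planar gradient: the terrain average equals
  # the terrain at the crown centre to first order
  cfg <- sceneConfig(treeRows = 1L, treeCols = 1L, gsd = 0.02,
                     d1Range = c(3, 3), d2Range = c(3, 3),
                     htRange = c(3, 3), hbMean = 0.7, hbSd = 0,
                     noiseAmplitude = 0, gradientX = 0.03, gradientY = 0.02)
  sc <- generateScene(cfg, seed = 2)
  ndsm <- computeNdsm(sc$dsm, sc$dtm_true)
  segs <- labelCrowns(localThreshold(ndsm, segmentationParams(
    "fixed", heightThreshold = 0.5)), ndsm)
  h <- treeHeight(sc$dsm, sc$dtm_true, segs, 1, ringWidth = 2)
  expect_lt(abs(h - 3.0), 0.02)
})

test_that("per-tree heights track the truth on the default scene", {
  an <- defaultAnalysis()
  err <- an$merged$height_m - an$merged$ht
  expect_lt(max(abs(err)), 2 * an$scene$dsm@pixelSizeX + 0.05) # gsd + DTM noise
  expect_lt(sqrt(mean(err^2)), 2 * an$scene$dsm@pixelSizeX)
})

test_that("equivalent-circle diameter inverts the footprint area", {
  expect_equal(crownDiameter(pi * 1.5^2), 3.0)
  expect_equal(crownDiameter(4e-4), 2 * sqrt(4e-4 / pi)) # one 2 cm pixel
  expect_equal(crownDiameter(4e-4), 0.02257, tolerance = 1e-3)
  # elliptic footprint -> geometric-mean diameter
  expect_equal(crownDiameter(pi * 1.5 * 1.0), 2 * sqrt(1.5), tolerance = 1e-12)
  expect_error(crownDiameter(0), "> 0")
})

test_that("total volume sums pixel prisms and flags nodata", {
  v <- matrix(0, 20, 20)
  v[6:15, 6:15] <- 2.5 # 100 pixels
  g <- rasterGrid(v, pixelSize = 0.02, units = "m")
  segs <- labelCrowns(v > 0.5, g, minArea = 0) # 0.04 m2 block, keep it
  expect_equal(totalVolume(g, segs, 1), 100 * 4e-4 * 2.5)
  # a label with no pixels integrates to zero
  expect_equal(totalVolume(g, segs, 99), 0)
  v[7, 7] <- NA
  g2 <- withValues(g, v)
  expect_warning(tv <- totalVolume(g2, segs, 1), "nodata")
  expect_equal(tv, 99 * 4e-4 * 2.5)
})

test_that("below-canopy prism and net volume follow the clamp rules", {
  expect_equal(belowCanopyVolume(7.0, 0.7), 4.9)
  expect_equal(belowCanopyVolume(7.0, 0), 0)
  expect_error(belowCanopyVolume(7.0, -0.1), ">= 0")
  expect_equal(netCanopyVolume(10.0, 4.9), 5.1)
  expect_warning(net <- netCanopyVolume(1.0, 2.0), "clamped")
  expect_equal(net, 0)
})

test_that("ellipsoid volume and TCSA evaluate their closed forms", {
  expect_equal(ellipsoidVolume(2, 2, 2.7, 0.7), 4 * pi / 3)
  expect_equal(ellipsoidVolume(3, 2, 3.4, 0.7),
               (4 * pi / 3) * 1.5 * 1.0 * 1.35)
  expect_equal(ellipsoidVolume(3, 2, 3.4, 0.7), 8.4823, tolerance = 1e-4)
  expect_error(ellipsoidVolume(2, 2, 1.0, 1.0), "exceed")
  expect_equal(tcsa(2 * pi), pi)
  expect_equal(tcsa(0.40), 0.40^2 / (4 * pi))
  expect_equal(tcsa(0.40), 0.012732, tolerance = 1e-4)
  expect_error(tcsa(0), "> 0")
})

test_that("volume error vs the closed form shrinks with resolution", {
  errs <- vapply(c(0.04, 0.02, 0.01), function(g) {
    sc <- canonicalCrownScene(g)
    abs(netVolumeOfScene(sc) / sc$trees$surface_integral_volume - 1)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.02)
})

test_that("per-tree clearances are looked up strictly", {
  an <- defaultAnalysis()
  dTable <- an$scene$trees[, c("tree_id", "d")]
  dTable <- dTable[dTable$tree_id != "T07", ] # drop one tree
  expect_error(
    treeMetrics(an$ndsm, an$scene$dsm, an$dtm, an$segs,
                dTable = dTable, matching = an$matching),
    "T07")
})

test_that("net volume recovery against truth meets the desk-scale bound", {
  an <- defaultAnalysis()
  f <- fitOriginForced(an$merged$surface_integral_volume,
                       an$merged$net_volume_m3)
  expect_gt(coef(f)[["slope"]], 0.95)
  expect_lt(coef(f)[["slope"]], 1.05)
  expect_gt(modelR2(f), 0.95)
  # net volumes sit in the expected orchard range
  expect_true(all(an$merged$net_volume_m3 > 1))
  expect_true(all(an$merged$net_volume_m3 < 25))
})
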