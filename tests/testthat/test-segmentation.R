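test_that("Niblack and Sauvola decisions match a brute-force oracle exactly", {
  set.seed(2024)
  for (rep in 1:20) {
    nr <- sample(8:32, 1); ncl <- sample(8:32, 1)
    v <- matrix(runif(nr * ncl, 0, 4), nr, ncl)
    if (rep %% 3 == 0) v[sample(length(v), 5)] <- NA
    window <- sample(c(3L, 5L, 7L, 9L), 1)
    g <- rasterGrid(v, pixelSize = 0.1, units = "m")
    kN <- runif(1, -0.4, 0.2)
    mN <- localThreshold(g, segmentationParams("niblack", window, k = kN,
                                               heightThreshold = -Inf))
    expect_identical(mN, bruteForceThreshold(v, "niblack", window, kN))
    kS <- runif(1, 0.1, 0.6)
    r <- diff(range(v, na.rm = TRUE)) / 2
    mS <- localThreshold(g, segmentationParams("sauvola", window, k = kS,
                                               r = r, heightThreshold = -Inf))
    expect_identical(mS, bruteForceThreshold(v, "sauvola", window, kS, r))
  }
})

test_that("constant grids threshold to all-background (tie rule)", {
  g <- rasterGrid(matrix(2.5, 15, 15), pixelSize = 0.1, units = "m")
  # s = 0 makes the Niblack threshold equal the constant value; with
  # k = 0 the Sauvola threshold does too. Equality must give background.
  mN <- localThreshold(g, segmentationParams("niblack", 7L,
                                             heightThreshold = -Inf))
  expect_false(any(mN))
  mS <- localThreshold(g, segmentationParams("sauvola", 7L, k = 0, r = 1,
                                             heightThreshold = -Inf))
  expect_false(any(mS))
})

test_that("a raised block on zero background is found by Niblack", {
  v <- matrix(0, 9, 9)
  v[4:6, 4:6] <- 3
  g <- rasterGrid(v, pixelSize = 0.5, units = "m")
  mask <- localThreshold(g, segmentationParams("niblack", 9L, k = -0.2,
                                               heightThreshold = -Inf))
  expect_identical(mask, bruteForceThreshold(v, "niblack", 9L, -0.2))
  expect_true(all(mask[4:6, 4:6]))
  # fixed threshold recovers the block exactly
  fixed <- localThreshold(g, segmentationParams("fixed", heightThreshold = 0.5))
  expect_identical(fixed, v > 0.5)
})

test_that("window larger than the grid errors", {
  g <- rasterGrid(matrix(runif(25), 5), pixelSize = 0.1)
  expect_error(localThreshold(g, segmentationParams("niblack", 101L)),
               "window")
})

test_that("labelling is 8-connected and respects the area filter", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE # touch diagonally -> one component
  m[5, 5:6] <- TRUE                # separate 2-pixel blob
  g <- rasterGrid(matrix(0, 6, 6), pixelSize = 1, units = "m")
  segs <- labelCrowns(m, g, minArea = 0.5)
  expect_equal(length(segs), 2L)
  lab <- gridValues(labelRaster(segs))
  expect_equal(lab[2, 2], lab[3, 3]) # merged across the diagonal
  expect_true(lab[5, 5] != lab[2, 2])
  # labels follow raster-scan order of the first pixel
  expect_equal(lab[2, 2], 1)
  expect_equal(lab[5, 5], 2)
  # min_area = 10 pixels removes a 2-pixel blob entirely
  m2 <- matrix(FALSE, 6, 6); m2[1, 1:2] <- TRUE
  expect_equal(length(labelCrowns(m2, g, minArea = 10)), 0L)
  expect_equal(segmentTable(labelCrowns(m2, g, minArea = 10))$label,
               integer(0))
})

test_that("segment footprints account area exactly", {
  an <- defaultAnalysis()
  tab <- segmentTable(an$segs)
  expect_equal(tab$footprint_area, tab$n_pixels * pixelArea(an$ndsm))
  # masks of distinct segments are disjoint by construction of a label
  # raster; check the label counts match
  lab <- gridValues(labelRaster(an$segs))
  expect_equal(as.integer(table(lab[lab > 0])), tab$n_pixels)
})

test_that("default segmentation recovers every crown of the default scene", {
  an <- defaultAnalysis()
  expect_equal(length(an$segs), 15L)
  expect_equal(nrow(an$matching$pairs), 15L)
  expect_equal(length(an$matching$unmatchedTrees), 0L)
  expect_equal(length(an$matching$unmatchedSegments), 0L)
})

test_that("matching reports extra truth rows and resolves ties deterministically", {
  an <- defaultAnalysis()
  trees <- an$scene$trees
  ghost <- trees[1, ]
  ghost$tree_id <- "GHOST"
  ghost$x <- -50; ghost$y <- -50 # outside the raster
  mt <- matchSegmentsToTruth(an$segs, rbind(trees, ghost))
  expect_equal(nrow(mt$pairs), 15L)
  expect_equal(mt$unmatchedTrees, "GHOST")

  # two segments equidistant from one tree: lower label wins
  m <- matrix(FALSE, 11, 11)
  m[2:3, 2:3] <- TRUE
  m[9:10, 2:3] <- TRUE
  g <- rasterGrid(matrix(0, 11, 11), pixelSize = 1, units = "m")
  segs <- labelCrowns(m, g, minArea = 0.5)
  tr <- data.frame(tree_id = "A", x = 2.5, y = 5.5) # halfway between
  mt2 <- matchSegmentsToTruth(segs, tr, maxDist = 10)
  expect_equal(mt2$pairs$label, 1L)
})

test_that("raising the fixed threshold never grows a footprint", {
  an <- defaultAnalysis()
  areas <- sapply(c(0.5, 0.8, 1.2, 1.6), function(thr) {
    segs <- labelCrowns(
      localThreshold(an$ndsm, segmentationParams("fixed",
                                                 heightThreshold = thr)),
      an$ndsm)
    sum(segmentTable(segs)$footprint_area)
  })
  expect_true(all(diff(areas) <= 0))
})
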