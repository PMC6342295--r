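test_that("single-crown scene has the configured apex height", {
  cfg <- sceneConfig(treeRows = 1L, treeCols = 1L, gsd = 0.02,
                     d1Range = c(2, 2), d2Range = c(2, 2),
                     htRange = c(2.7, 2.7), hbMean = 0.7, hbSd = 0,
                     noiseAmplitude = 0, gradientX = 0, gradientY = 0)
  sc <- generateScene(cfg, seed = 1)
  hmax <- max(gridValues(sc$dsm) - gridValues(sc$dtm_true))
  # the apex sits at Hb + 2c = Ht above ground
  expect_lt(abs(hmax - 2.7), 2 * cfg@gsd)
})

test_that("default scene carries 15 trees with consistent closed-form truth", {
  sc <- defaultAnalysis()$scene
  tr <- sc$trees
  expect_equal(nrow(tr), 15L)
  expect_equal(tr$ellipsoid_volume,
               ellipsoidVolume(tr$d1, tr$d2, tr$ht, tr$hb))
  # solid crowns: the nadir surface integral is exactly 5/4 of the
  # ellipsoid volume
  expect_equal(tr$surface_integral_volume, 1.25 * tr$ellipsoid_volume)
  expect_true(all(tr$hb < tr$ht))
})

test_that("numeric quadrature confirms the 5/3 pi a b c surface integral", {
  # independent oracle: integrate z_top - Hb over the footprint on a fine
  # subgrid of one crown
  a <- 1.5; b <- 1.0; cc <- 1.35
  h <- 0.002
  xs <- seq(-a, a, by = h); ys <- seq(-b, b, by = h)
  r2 <- outer((ys / b)^2, (xs / a)^2, "+")
  inside <- r2 <= 1
  z <- cc * (1 + sqrt(pmax(1 - r2, 0)))
  quad <- sum(z[inside]) * h^2
  expect_equal(quad, (5 / 3) * pi * a * b * cc, tolerance = 1e-3)
})

test_that("crown surface stays within the physical height bounds", {
  sc <- defaultAnalysis()$scene
  rel <- gridValues(sc$dsm) - gridValues(sc$dtm_true)
  tr <- sc$trees
  crown <- rel > 1e-9
  expect_true(all(rel[crown] >= min(tr$hb) - 1e-9))
  expect_true(max(rel) <= max(tr$ht) + 1e-9)
})

test_that("scenes are reproducible by seed", {
  cfg <- sceneConfig(gsd = 0.1)
  a <- generateScene(cfg, seed = 11)
  b <- generateScene(cfg, seed = 11)
  d <- generateScene(cfg, seed = 12)
  expect_identical(gridValues(a$dsm), gridValues(b$dsm))
  expect_identical(a$trees, b$trees)
  expect_false(identical(gridValues(a$nir), gridValues(d$nir)))
  expect_false(identical(a$trees, d$trees))
})

test_that("configurations allowing crown overlap are rejected", {
  expect_error(sceneConfig(d1Range = c(5, 6)), "overlap")
  expect_error(sceneConfig(spacingX = 3, d1Range = c(3.2, 3.5)), "overlap")
})

test_that("hollow-core crowns lose volume relative to solid ones", {
  mk <- function(hcf) {
    cfg <- sceneConfig(treeRows = 1L, treeCols = 1L, gsd = 0.02,
                       d1Range = c(3, 3), d2Range = c(3, 3),
                       htRange = c(3, 3), hbMean = 0.7, hbSd = 0,
                       noiseAmplitude = 0, gradientX = 0, gradientY = 0,
                       hollowCoreFraction = hcf)
    generateScene(cfg, seed = 5)
  }
  solid <- mk(0); hollow <- mk(0.5)
  netSolid <- netVolumeOfScene(solid)
  netHollow <- netVolumeOfScene(hollow)
  expect_lt(netHollow, netSolid)
  # the analytic truth tracks the depression
  expect_lt(hollow$trees$surface_integral_volume,
            solid$trees$surface_integral_volume)
  expect_equal(netHollow, hollow$trees$surface_integral_volume,
               tolerance = 0.01)
  # reproduces the field-method overestimation: the ellipsoid formula
  # cannot see the empty vase core
  expect_lt(netHollow, 1.25 * hollow$trees$ellipsoid_volume)
})

test_that("SWP series respect the regime envelopes", {
  for (seed in 1:5) {
    irr <- generateSwpSeries("irrigated", seed = seed)
    rf <- generateSwpSeries("rainfed", seed = seed)
    expect_true(all(swp(irr) >= -2.2))
    expect_lte(min(swp(rf)), -4.0)
  }
  # zero noise is deterministic
  a <- generateSwpSeries("rainfed", seed = 1, noiseSd = 0)
  b <- generateSwpSeries("rainfed", seed = 99, noiseSd = 0)
  expect_identical(swp(a), swp(b))
  expect_error(generateSwpSeries("irrigated", doyGrid = integer(0)),
               "non-empty")
})
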