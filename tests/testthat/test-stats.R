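test_that("residual RMSE follows its definition", {
  expect_equal(residualRmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(residualRmse(c(3, 4), c(2, 4)), sqrt(0.5))
  expect_equal(residualRmse(c(5, 6, 7), c(5, 6, 7) - 0.3), 0.3)
  # scale equivariance
  set.seed(1)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(residualRmse(3 * x, 3 * y), 3 * residualRmse(x, y))
  expect_error(residualRmse(1:3, 1:4), "same length")
})

test_that("origin-forced fit has the closed-form slope and uncentered R2", {
  f <- fitOriginForced(1:10, 0.9 * (1:10))
  expect_equal(coef(f)[["slope"]], 0.9)
  expect_equal(modelRmse(f), 0)
  expect_equal(modelR2(f), 1)
  f2 <- fitOriginForced(c(1, 2, 3), c(2, 4, 7))
  expect_equal(coef(f2)[["slope"]], 31 / 14)
  expect_equal(f2@r2Type, "uncentered")
  f3 <- fitOriginForced(2, 4)
  expect_equal(coef(f3)[["slope"]], 2)
  expect_equal(modelR2(f3), 1)
  expect_error(fitOriginForced(c(0, 0), c(1, 2)), "all-zero")
})

test_that("least-squares fits agree with a brute-force parameter search", {
  refineSearch <- function(sse, centers, widths, iters = 40, npts = 41) {
    # halve the search box each round: slow enough to follow the
    # correlated intercept/slope valley without losing the optimum
    for (it in seq_len(iters)) {
      grids <- mapply(function(c0, w) seq(c0 - w, c0 + w, length.out = npts),
                      centers, widths, SIMPLIFY = FALSE)
      cand <- expand.grid(grids)
      vals <- apply(cand, 1, sse)
      best <- which.min(vals)
      centers <- as.numeric(cand[best, ])
      widths <- widths * 0.5
    }
    centers
  }
  set.seed(42)
  x <- runif(8, 0, 10); y <- 1.3 * x + rnorm(8)
  bf <- refineSearch(function(p) sum((y - p * x)^2), 1, 3)
  expect_equal(coef(fitOriginForced(x, y))[["slope"]], bf, tolerance = 1e-6)

  y2 <- -0.5 + 2.1 * x + rnorm(8)
  bf2 <- refineSearch(function(p) sum((y2 - p[1] - p[2] * x)^2),
                      c(0, 2), c(3, 3))
  f <- fitOrdinary(x, y2)
  expect_equal(coef(f)[["intercept"]], bf2[1], tolerance = 1e-5)
  expect_equal(coef(f)[["slope"]], bf2[2], tolerance = 1e-5)
})

test_that("ordinary fit recovers exact lines and rejects degeneracy", {
  x <- seq(1, 5, by = 0.5)
  f <- fitOrdinary(x, 1.06 * x - 0.10)
  expect_equal(coef(f)[["slope"]], 1.06)
  expect_equal(coef(f)[["intercept"]], -0.10)
  expect_equal(modelR2(f), 1)
  expect_error(fitOrdinary(rep(2, 5), 1:5), "degenerate")
  expect_error(fitOrdinary(1:2, 1:2), "at least 3")
  # independence: slope and R2 near zero at large n
  set.seed(5)
  xi <- rnorm(2000); yi <- rnorm(2000)
  fi <- fitOrdinary(xi, yi)
  expect_lt(abs(coef(fi)[["slope"]]), 0.08)
  expect_lt(modelR2(fi), 0.01)
})

test_that("bilinear fit recovers a constructed breakpoint", {
  x <- seq(-5, 0, length.out = 60)
  cTrue <- -2.5
  y <- 1.0 * pmax(x - cTrue, 0) + 0.3
  f <- fitBilinear(x, y)
  step <- diff(range(x)) / 199
  expect_lt(abs(breakpoint(f) - cTrue), step + 1e-9)
  expect_equal(coef(f)[["slope1"]], 0, tolerance = 0.02)
  expect_equal(coef(f)[["slope2"]], 1, tolerance = 0.02)
  expect_gt(modelR2(f), 0.999)
  expect_true(f@breakpointIdentifiable)
})

test_that("a pure line is flagged breakpoint-non-identifiable", {
  x <- seq(0, 10, length.out = 30)
  f <- fitBilinear(x, 2 * x + 1)
  expect_false(f@breakpointIdentifiable)
  expect_equal(coef(f)[["slope1"]], coef(f)[["slope2"]], tolerance = 1e-6)
  expect_error(fitBilinear(x, 2 * x + 1, grid = c(-5, 15)), "outside")
  expect_error(fitBilinear(1:4, 1:4), "at least 5")
})

test_that("breakpoint recovery is unbiased under noise", {
  x <- seq(-5, 0, length.out = 40)
  cTrue <- -2.5
  mu <- 0.8 * pmax(x - cTrue, 0) - 1
  set.seed(11)
  est <- replicate(100, {
    y <- mu + rnorm(length(x), 0, 0.05)
    breakpoint(fitBilinear(x, y, grid = seq(-5, 0, length.out = 100)))
  })
  # Monte-Carlo error of the mean
  expect_lt(abs(mean(est) - cTrue), 3 * sd(est) / sqrt(length(est)) + 0.06)
})

test_that("multiple regression recovers an exact coefficient triple", {
  set.seed(3)
  w <- runif(20, -3.2, -0.7) # daily WSI range
  v <- runif(20, 0.3, 0.7)   # NDVI range
  y <- -0.03 * w + 1.21 * v - 0.423
  f <- fitMultiple(y, w, v, names2 = c("daily_wsi", "ndvi"))
  expect_equal(coef(f)[["daily_wsi"]], -0.03, tolerance = 1e-9)
  expect_equal(coef(f)[["ndvi"]], 1.21, tolerance = 1e-9)
  expect_equal(coef(f)[["intercept"]], -0.423, tolerance = 1e-9)
  expect_equal(modelR2(f), 1)
  expect_error(fitMultiple(y, w, 2 * w + 1), "rank-deficient")
})

test_that("multiple-regression confidence intervals cover at the nominal rate", {
  set.seed(21)
  hits <- replicate(200, {
    x1 <- rnorm(30); x2 <- rnorm(30)
    y <- 1 + 0.5 * x1 - 0.8 * x2 + rnorm(30, 0, 0.5)
    ci <- confint(stats::lm(y ~ x1 + x2))["x1", ]
    ci[1] <= 0.5 && 0.5 <= ci[2]
  })
  expect_gt(mean(hits), 0.90)
  expect_lt(mean(hits), 0.99)
})
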