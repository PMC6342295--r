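## Validation statistics: the fits used to compare image-based estimates
## with field measurements and to relate growth to water status.

#' RMSE of residuals
#'
#' Residuals are measured minus estimated values per tree; the root mean
#' square error uses divisor n (not n - p).
#'
#' @param measured,estimated numeric vectors of equal length >= 1.
#' @return RMSE in the units of the inputs.
#' @examples
#' residualRmse(c(3, 4), c(2, 4)) # sqrt(0.5)
#' @export
residualRmse <- function(measured, estimated) {
  if (length(measured) != length(estimated))
    stop("measured and estimated must have the same length")
  if (!length(measured)) stop("empty input")
  sqrt(mean((measured - estimated)^2))
}

.regResult <- function(model, coefs, y, yhat, r2, r2Type = "centered",
                       breakpoint = NA_real_, identifiable = TRUE) {
  new("RegressionResult", model = model, coefficients = coefs,
      breakpoint = breakpoint, breakpointIdentifiable = identifiable,
      r2 = r2, r2Type = r2Type,
      rmse = sqrt(mean((y - yhat)^2)), n = length(y))
}

setMethod("show", "RegressionResult", function(object) {
  cat("RegressionResult (", object@model, "): n = ", object@n, "\n", sep = "")
  co <- object@coefficients
  cat("  coefficients:",
      paste(names(co), signif(co, 5), sep = " = ", collapse = ", "), "\n")
  if (!is.na(object@breakpoint))
    cat("  breakpoint  :", signif(object@breakpoint, 5),
        if (!object@breakpointIdentifiable) "(not identifiable)" else "", "\n")
  cat("  R2 (", object@r2Type, "): ", signif(object@r2, 5),
      "   RMSE: ", signif(object@rmse, 5), "\n", sep = "")
})

#' @describeIn RegressionResult-class fitted coefficients.
#' @param object a \linkS4class{RegressionResult}.
#' @export
setMethod("coef", "RegressionResult", function(object) object@coefficients)

#' @rdname RegressionResult-class
#' @param x a \linkS4class{RegressionResult}.
#' @export
modelR2 <- function(x) x@r2

#' @rdname RegressionResult-class
#' @export
modelRmse <- function(x) x@rmse

#' @rdname RegressionResult-class
#' @export
breakpoint <- function(x) x@breakpoint

# R-squared from an lm fit; summary.lm warns on exact (zero-residual)
# data, which is a legitimate input for calibration checks here.
.quietR2 <- function(fit) {
  withCallingHandlers(
    summary(fit)$r.squared,
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

#' Linear fit forced through the origin
#'
#' Slope \code{sum(x * y) / sum(x^2)}; since the model has no intercept,
#' the reported R2 is the uncentered form
#' \code{1 - sum((y - yhat)^2) / sum(y^2)}, which is the convention for
#' origin-forced calibration fits (the centered form can be negative).
#'
#' @param x,y numeric vectors, \code{sum(x^2) > 0}.
#' @return a \linkS4class{RegressionResult}.
#' @examples
#' coef(fitOriginForced(1:10, 0.9 * (1:10)))
#' @export
fitOriginForced <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1L)
  sxx <- sum(x^2)
  if (sxx == 0) stop("all-zero predictor: slope undefined")
  slope <- sum(x * y) / sxx
  yhat <- slope * x
  r2 <- if (sum(y^2) > 0) 1 - sum((y - yhat)^2) / sum(y^2) else 1
  .regResult("origin_forced", c(slope = slope), y, yhat, r2,
             r2Type = "uncentered")
}

#' Ordinary least-squares line
#'
#' Intercept + slope fit via \code{stats::lm}, with centered R2 and the
#' residual RMSE (divisor n).
#'
#' @param x,y numeric vectors, >= 3 points, \code{var(x) > 0}.
#' @return a \linkS4class{RegressionResult}.
#' @export
fitOrdinary <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 points")
  if (stats::var(x) == 0) stop("degenerate predictor: var(x) = 0")
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  yhat <- stats::fitted(fit)
  r2 <- .quietR2(fit)
  .regResult("ordinary", c(intercept = unname(co[1]), slope = unname(co[2])),
             y, yhat, r2)
}

#' Continuous two-segment (bilinear) regression
#'
#' Fits \code{y = a + b1 * x + b2 * max(x - c, 0)} by profiling the
#' breakpoint c over a deterministic grid: at each candidate the model is
#' linear and solved by least squares; the candidate minimizing the SSE
#' wins. When the profiled SSE is flat to within numerical noise (the
#' data are a single line) the breakpoint is flagged non-identifiable.
#'
#' @param x,y numeric vectors, >= 5 points.
#' @param grid candidate breakpoints; default 200 points spanning
#'   \code{range(x)}.
#' @return a \linkS4class{RegressionResult} with coefficients
#'   \code{intercept}, \code{slope1} (left), \code{slope2} (right) and
#'   the breakpoint.
#' @export
fitBilinear <- function(x, y, grid = NULL) {
  stopifnot(length(x) == length(y))
  if (length(x) < 5L) stop("need at least 5 points")
  if (is.null(grid)) grid <- seq(min(x), max(x), length.out = 200L)
  if (min(grid) < min(x) - 1e-12 || max(grid) > max(x) + 1e-12)
    stop("breakpoint grid extends outside the range of x")
  best <- NULL
  sses <- numeric(length(grid))
  for (i in seq_along(grid)) {
    cc <- grid[i]
    xp <- pmax(x - cc, 0)
    fit <- stats::lm(y ~ x + xp)
    sse <- sum(stats::residuals(fit)^2)
    sses[i] <- sse
    if (is.null(best) || sse < best$sse - 1e-12)
      best <- list(sse = sse, c = cc, fit = fit)
  }
  identifiable <- (max(sses) - min(sses)) >
    1e-8 * max(max(sses), .Machine$double.eps)
  co <- stats::coef(best$fit)
  co[is.na(co)] <- 0
  yhat <- stats::fitted(best$fit)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - best$sse / sst else 1
  .regResult("bilinear",
             c(intercept = unname(co[1]), slope1 = unname(co[2]),
               slope2 = unname(co[2]) + unname(co[3])),
             y, yhat, r2, breakpoint = best$c, identifiable = identifiable)
}

#' Two-predictor multiple regression
#'
#' Least-squares fit of \code{y ~ x1 + x2} (e.g. monthly trunk growth on
#' daily water stress integral and NDVI), with centered R2.
#'
#' @param y response vector.
#' @param x1,x2 predictor vectors; the design must be full rank.
#' @param names2 optional names for the two coefficients.
#' @return a \linkS4class{RegressionResult} with coefficients
#'   \code{intercept}, then one per predictor.
#' @export
fitMultiple <- function(y, x1, x2, names2 = c("x1", "x2")) {
  stopifnot(length(y) == length(x1), length(y) == length(x2))
  if (length(y) < 4L) stop("need at least 4 points")
  X <- cbind(1, x1, x2)
  if (qr(X)$rank < 3L)
    stop("rank-deficient design (collinear predictors)")
  fit <- stats::lm(y ~ x1 + x2)
  co <- stats::coef(fit)
  yhat <- stats::fitted(fit)
  r2 <- .quietR2(fit)
  coefs <- c(unname(co[1]), unname(co[2]), unname(co[3]))
  names(coefs) <- c("intercept", names2)
  .regResult("multiple", coefs, y, yhat, r2)
}
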