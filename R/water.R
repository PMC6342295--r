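## Tree water status: Myers' water stress integral and the irrigation
## arithmetic of a drip-irrigated orchard.

#' Construct a stem water potential series
#'
#' @param treeId tree or treatment identifier.
#' @param doy integer days of year, strictly increasing.
#' @param swp stem water potential (MPa, <= 0), same length.
#' @return an \linkS4class{SWPSeries}.
#' @export
swpSeries <- function(treeId = "tree", doy, swp) {
  obj <- new("SWPSeries", treeId = as.character(treeId),
             doy = as.integer(doy), swp = as.numeric(swp))
  validObject(obj)
  obj
}

#' @rdname SWPSeries-class
#' @param x an \linkS4class{SWPSeries}.
#' @export
doy <- function(x) x@doy

#' @rdname SWPSeries-class
#' @export
swp <- function(x) x@swp

setMethod("show", "SWPSeries", function(object) {
  cat("SWPSeries '", object@treeId, "': ", length(object@doy),
      " measurements, DOY ", min(object@doy), "-", max(object@doy),
      ", SWP [", signif(min(object@swp), 3), ", ",
      signif(max(object@swp), 3), "] MPa\n", sep = "")
})

setMethod("show", "WSIResult", function(object) {
  cat("Water stress integral: ", signif(object@wsi, 4), " MPa d over ",
      object@nDays, " d (daily ", signif(object@dailyWsi, 4),
      " MPa; reference ", signif(object@cRef, 4), " MPa, n = ",
      object@n, ")\n", sep = "")
})

#' @rdname WSIResult-class
#' @param x a \linkS4class{WSIResult}.
#' @export
wsi <- function(x) x@wsi

#' @rdname WSIResult-class
#' @export
dailyWsi <- function(x) x@dailyWsi

#' Water stress integral (Myers)
#'
#' Accumulates the deviation of stem water potential from its seasonal
#' maximum over an analysis window:
#' \deqn{WSI = \left|\sum_i (\bar\Psi_{i,i+1} - c)\, n_i\right|}
#' where \eqn{\bar\Psi_{i,i+1}} is the mean SWP of two consecutive
#' measurements, \eqn{c} the maximum (least negative) SWP within the
#' window, and \eqn{n_i} the interval length in days. The integral is
#' reported positive (MPa d); the signed daily value is
#' \code{-wsi / nDays} (MPa). By default \eqn{c} is taken per series
#' ("per tree"); pass a fixed \code{cRef} to use a common treatment
#' reference instead.
#'
#' @param series an \linkS4class{SWPSeries}.
#' @param window \code{c(startDoy, endDoy)} analysis window; records
#'   outside it are ignored with a warning. Default spans the series.
#' @param cRef optional fixed reference SWP (MPa); default: the window
#'   maximum of the series.
#' @return a \linkS4class{WSIResult}.
#' @examples
#' s <- swpSeries("t", c(0, 10, 20), c(-1, -2, -3))
#' wsi(waterStressIntegral(s)) # 20 MPa d
#' @export
waterStressIntegral <- function(series, window = NULL, cRef = NULL) {
  stopifnot(is(series, "SWPSeries"))
  t <- series@doy; p <- series@swp
  if (!is.null(window)) {
    inside <- t >= window[1] & t <= window[2]
    if (any(!inside))
      warning(sum(!inside), " record(s) outside the analysis window ignored")
    t <- t[inside]; p <- p[inside]
  }
  if (length(t) < 2L)
    stop("need at least 2 SWP records inside the window")
  cc <- if (is.null(cRef)) max(p) else cRef
  n <- diff(t)
  psiBar <- (p[-1] + p[-length(p)]) / 2
  total <- abs(sum((psiBar - cc) * n))
  nDays <- t[length(t)] - t[1]
  new("WSIResult", wsi = total, dailyWsi = -total / nDays,
      nDays = as.numeric(nDays), cRef = cc, n = length(t))
}

#' Irrigation requirement from effective evapotranspiration
#'
#' Scales effective evapotranspiration by the crop coefficient Kc and
#' the ground-cover coefficient Kr: \code{IR = ETeff * Kc * Kr}.
#' Defaults are the olive-orchard values Kc = 0.55, Kr = 0.46.
#'
#' @param etEff effective evapotranspiration (mm), >= 0.
#' @param kc crop coefficient.
#' @param kr ground-cover coefficient.
#' @return irrigation requirement (mm).
#' @examples
#' irrigationRequirement(100) # 25.3 mm
#' @export
irrigationRequirement <- function(etEff, kc = 0.55, kr = 0.46) {
  if (any(etEff < 0)) stop("effective evapotranspiration must be >= 0")
  stopifnot(kc > 0, kr > 0)
  etEff * kc * kr
}

#' Per-tree irrigation volume from a per-hectare volume
#'
#' Divides a seasonal per-hectare irrigation volume by the planting
#' density and converts to litres:
#' \code{L/tree = volume_per_ha / (10000 / (sx * sy)) * 1000}. At
#' 5 x 5 m spacing (400 trees/ha), 1348 m^3/ha corresponds to 3370
#' L/tree.
#'
#' @param volumePerHa seasonal irrigation volume (m^3 ha^-1).
#' @param spacingX,spacingY planting distances (m), > 0.
#' @return litres per tree.
#' @examples
#' perTreeIrrigation(1348, 5, 5) # 3370
#' @export
perTreeIrrigation <- function(volumePerHa, spacingX = 5, spacingY = 5) {
  if (spacingX <= 0 || spacingY <= 0) stop("tree spacing must be > 0")
  treesPerHa <- 10000 / (spacingX * spacingY)
  volumePerHa / treesPerHa * 1000
}
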