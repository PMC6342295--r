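## Bowyer-Watson Delaunay triangulation.
##
## Ground points sampled on a regular grid are exactly cocircular in
## groups of four, which makes the in-circle predicate ambiguous; a
## deterministic symbolic jitter of ~1e-9 of the point-cloud extent
## breaks ties without measurably moving the interpolated surface.

.detJitter <- function(keys, scale) {
  scale * 1e-9 * (((sin(keys * 12.9898) * 43758.5453) %% 1) - 0.5)
}

.circumcircle <- function(px, py) {
  ax <- px[1]; ay <- py[1]; bx <- px[2]; by <- py[2]; cx <- px[3]; cy <- py[3]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < .Machine$double.eps * 100 * max(abs(c(px, py)), 1))
    return(NULL)
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  c(ux, uy, (ux - ax)^2 + (uy - ay)^2)
}

# Returns an integer matrix (ntri x 3) of point indices, or stops if the
# point set is degenerate (fewer than 3 points or all collinear).
.delaunay <- function(x, y) {
  n <- length(x)
  if (n < 3L) stop("need at least 3 ground points")
  scale <- max(diff(range(x)), diff(range(y)))
  if (scale == 0) stop("degenerate ground point set")
  x <- x + .detJitter(seq_len(n), scale)
  y <- y + .detJitter(seq_len(n) * 7.13 + 3.7, scale)

  # super-triangle comfortably enclosing everything
  cx <- mean(range(x)); cy <- mean(range(y)); m <- 20 * scale
  px <- c(x, cx - m, cx + m, cx)
  py <- c(y, cy - m, cy - m, cy + m)
  sup <- n + 1:3

  tri <- matrix(sup, 1L, 3L)
  cc0 <- .circumcircle(px[sup], py[sup])
  circ <- matrix(cc0, 1L, 3L, byrow = TRUE)

  for (p in seq_len(n)) {
    bad <- (px[p] - circ[, 1])^2 + (py[p] - circ[, 2])^2 <=
      circ[, 3] * (1 + 1e-12)
    if (!any(bad)) next # cannot happen inside the super-triangle
    badTri <- tri[bad, , drop = FALSE]
    edges <- rbind(badTri[, c(1, 2), drop = FALSE],
                   badTri[, c(2, 3), drop = FALSE],
                   badTri[, c(3, 1), drop = FALSE])
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    boundary <- edges[!(key %in% key[duplicated(key)]), , drop = FALSE]
    tri <- tri[!bad, , drop = FALSE]
    circ <- circ[!bad, , drop = FALSE]
    newTri <- matrix(integer(), 0L, 3L)
    newCirc <- matrix(numeric(), 0L, 3L)
    for (e in seq_len(nrow(boundary))) {
      v <- c(boundary[e, ], p)
      cc <- .circumcircle(px[v], py[v])
      if (is.null(cc)) next
      newTri <- rbind(newTri, v)
      newCirc <- rbind(newCirc, cc)
    }
    tri <- rbind(tri, newTri)
    circ <- rbind(circ, newCirc)
  }

  keep <- tri[, 1] <= n & tri[, 2] <= n & tri[, 3] <= n
  out <- tri[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    stop("degenerate (collinear) ground point set: no triangulation exists")
  dimnames(out) <- NULL
  out
}

# Piecewise-linear interpolation of (x, y, z) samples on the cell centres
# of a template grid; cells outside the convex hull get the z of the
# nearest sample point.
.tinInterpolate <- function(x, y, z, template) {
  tri <- .delaunay(x, y)
  cc <- cellCoordinates(template)
  xs <- cc$x; ys <- cc$y
  nr <- length(ys); ncl <- length(xs)
  out <- matrix(NA_real_, nr, ncl)
  psx <- template@pixelSizeX; psy <- template@pixelSizeY
  for (t in seq_len(nrow(tri))) {
    i1 <- tri[t, 1]; i2 <- tri[t, 2]; i3 <- tri[t, 3]
    x1 <- x[i1]; y1 <- y[i1]; x2 <- x[i2]; y2 <- y[i2]; x3 <- x[i3]; y3 <- y[i3]
    det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
    if (abs(det) < 1e-14) next
    jj <- which(xs >= min(x1, x2, x3) - psx & xs <= max(x1, x2, x3) + psx)
    ii <- which(ys >= min(y1, y2, y3) - psy & ys <= max(y1, y2, y3) + psy)
    if (!length(jj) || !length(ii)) next
    qx <- matrix(xs[jj], length(ii), length(jj), byrow = TRUE)
    qy <- matrix(ys[ii], length(ii), length(jj))
    l1 <- ((y2 - y3) * (qx - x3) + (x3 - x2) * (qy - y3)) / det
    l2 <- ((y3 - y1) * (qx - x3) + (x1 - x3) * (qy - y3)) / det
    l3 <- 1 - l1 - l2
    eps <- 1e-9
    ok <- l1 >= -eps & l2 >= -eps & l3 >= -eps
    if (!any(ok)) next
    val <- l1 * z[i1] + l2 * z[i2] + l3 * z[i3]
    sub <- out[ii, jj, drop = FALSE]
    sub[ok] <- val[ok]
    out[ii, jj] <- sub
  }
  # nearest-sample extrapolation outside the hull
  miss <- which(is.na(out))
  if (length(miss)) {
    mi <- (miss - 1L) %% nr + 1L
    mj <- (miss - 1L) %/% nr + 1L
    qx <- xs[mj]; qy <- ys[mi]
    chunk <- 20000L
    for (s in seq(1L, length(miss), by = chunk)) {
      e <- min(s + chunk - 1L, length(miss))
      d2 <- outer(qx[s:e], x, function(a, b) (a - b)^2) +
            outer(qy[s:e], y, function(a, b) (a - b)^2)
      out[miss[s:e]] <- z[max.col(-d2, ties.method = "first")]
    }
  }
  out
}
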