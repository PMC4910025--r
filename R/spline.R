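#' Create a control polygon
#'
#' Builds the ordered closed ring of control points that a closed cubic
#' spline is fitted through. Coordinates are continuous pixel coordinates
#' (x = column, y = row, 0-based, origin top-left). Unless
#' \code{canonicalize = FALSE}, the ring orientation is normalized to
#' counterclockwise (positive shoelace area) by reversing the traversal
#' order while keeping the first point first; every outward-normal
#' computation in the package relies on this convention.
#'
#' @param points numeric n x 2 matrix (or coercible) of (x, y) points, n >= 3.
#' @param canonicalize reverse the ring if its signed area is negative.
#' @return a \linkS4class{ControlPolygon}.
#' @examples
#' square <- ControlPolygon(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)))
#' nControlPoints(square)
#' @export
ControlPolygon <- function(points, canonicalize = TRUE) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 2L)
    .stopInvalid("control points must have two columns (x, y)")
  if (nrow(points) < 3L)
    .stopInvalid(sprintf("at least 3 control points are required, got %d",
                         nrow(points)))
  if (!all(is.finite(points)))
    .stopInvalid("control point coordinates must be finite")
  dimnames(points) <- NULL
  if (canonicalize && .signedArea(points) < 0) {
    n <- nrow(points)
    points <- points[c(1L, rev(seq_len(n)[-1L])), , drop = FALSE]
  }
  new("ControlPolygon", points = points)
}

#' @rdname ControlPolygon-class
#' @export
setMethod("controlPoints", "ControlPolygon", function(object) object@points)

#' @rdname ControlPolygon-class
#' @export
setMethod("nControlPoints", "ControlPolygon", function(object) nrow(object@points))

setMethod("show", "ControlPolygon", function(object) {
  n <- nrow(object@points)
  cat(sprintf("ControlPolygon with %d points (closed ring, %s)\n", n,
              if (.signedArea(object@points) >= 0) "counterclockwise"
              else "clockwise"))
})

#' @rdname ClosedCubicSpline-class
#' @export
setMethod("controlPoints", "ClosedCubicSpline", function(object) object@points)

#' @rdname ClosedCubicSpline-class
#' @export
setMethod("nSegments", "ClosedCubicSpline", function(object) nrow(object@points))

setMethod("show", "ClosedCubicSpline", function(object) {
  cat(sprintf("ClosedCubicSpline with %d segments\n", nrow(object@points)))
})

# Solve the cyclic system for the joint derivatives of one coordinate:
# a matrix with 4 on the diagonal, 1 on the two cyclic off-diagonals,
# right-hand side 3 * (next - previous). The matrix is strictly diagonally
# dominant, so a plain dense solve is always well-posed; n is tens of
# points, so no specialized cyclic-tridiagonal path is needed.
.cyclicDerivSolve <- function(p) {
  n <- length(p)
  nxt <- .cycNext(n)
  prv <- .cycPrev(n)
  M <- matrix(0, n, n)
  M[cbind(seq_len(n), seq_len(n))] <- 4
  M[cbind(seq_len(n), nxt)] <- M[cbind(seq_len(n), nxt)] + 1
  M[cbind(seq_len(n), prv)] <- M[cbind(seq_len(n), prv)] + 1
  solve(M, 3 * (p[nxt] - p[prv]))
}

#' Fit a closed cubic spline through a control polygon
#'
#' Solves the cyclic linear system for the first derivatives at the joints
#' (x and y independently), then recovers the four cubic coefficients of
#' each segment from the end-point and end-derivative conditions. The
#' resulting curve interpolates every control point and is C2-continuous at
#' every joint, including the wrap-around joint.
#'
#' @param polygon a \linkS4class{ControlPolygon}.
#' @return a \linkS4class{ClosedCubicSpline}.
#' @examples
#' ring <- ControlPolygon(cbind(50 + 30 * cos(2 * pi * (0:15) / 16),
#'                              50 + 30 * sin(2 * pi * (0:15) / 16)))
#' sp <- fitClosedSpline(ring)
#' evalSpline(sp, 1, c(0, 0.5, 1))
#' @export
fitClosedSpline <- function(polygon) {
  if (!is(polygon, "ControlPolygon"))
    polygon <- ControlPolygon(polygon)
  pts <- polygon@points
  n <- nrow(pts)
  dx <- .cyclicDerivSolve(pts[, 1L])
  dy <- .cyclicDerivSolve(pts[, 2L])
  si <- .cycPrev(n)  # segment i starts at P_{i-1}, with P_0 = P_n
  coef1 <- function(p, d) {
    b1 <- p[si]
    b2 <- d[si]
    b3 <- 3 * p - d - 2 * d[si] - 3 * p[si]
    b4 <- d + d[si] + 2 * p[si] - 2 * p
    cbind(b1, b2, b3, b4, deparse.level = 0)
  }
  new("ClosedCubicSpline",
      coefX = coef1(pts[, 1L], dx),
      coefY = coef1(pts[, 2L], dy),
      points = pts)
}

#' Evaluate a closed cubic spline
#'
#' Returns the point(s) of segment \code{segment} at parameter value(s)
#' \code{t} in [0, 1]; \code{t = 0} is the segment's start control point and
#' \code{t = 1} its end control point.
#'
#' @param spline a \linkS4class{ClosedCubicSpline}.
#' @param segment segment index in 1..nSegments.
#' @param t numeric vector of parameter values in [0, 1].
#' @return a length(t) x 2 matrix of (x, y).
#' @export
evalSpline <- function(spline, segment, t) {
  n <- nSegments(spline)
  if (length(segment) != 1L || segment < 1L || segment > n || segment != round(segment))
    .stopInvalid(sprintf("segment index must be in 1..%d", n))
  if (any(t < 0 | t > 1))
    .stopInvalid("t must lie in [0, 1]")
  cx <- spline@coefX[segment, ]
  cy <- spline@coefY[segment, ]
  cbind(x = cx[1L] + t * (cx[2L] + t * (cx[3L] + t * cx[4L])),
        y = cy[1L] + t * (cy[2L] + t * (cy[3L] + t * cy[4L])))
}

#' Unit tangent and outward normal of a spline
#'
#' The tangent is the normalized parameter derivative (dx/dt, dy/dt); the
#' normal is the tangent rotated so that, for the canonical counterclockwise
#' ring, it points outward (away from the enclosed region):
#' \code{normal = (tangent_y, -tangent_x)}. The normal at control point
#' \eqn{P_k} is conventionally evaluated at t = 1 of segment k.
#'
#' @inheritParams evalSpline
#' @param t a single parameter value in [0, 1].
#' @return list with unit \code{tangent} and \code{normal} (length-2 each).
#' @export
splineTangentNormal <- function(spline, segment, t) {
  n <- nSegments(spline)
  if (segment < 1L || segment > n)
    .stopInvalid(sprintf("segment index must be in 1..%d", n))
  if (t < 0 || t > 1)
    .stopInvalid("t must lie in [0, 1]")
  cx <- spline@coefX[segment, ]
  cy <- spline@coefY[segment, ]
  dx <- cx[2L] + t * (2 * cx[3L] + 3 * t * cx[4L])
  dy <- cy[2L] + t * (2 * cy[3L] + 3 * t * cy[4L])
  len <- sqrt(dx * dx + dy * dy)
  if (!is.finite(len) || len < 1e-12)
    .stopDegenerate("zero-length spline derivative; tangent undefined")
  tg <- c(dx, dy) / len
  list(tangent = tg, normal = c(tg[2L], -tg[1L]))
}

# Outward unit normals at every control point P_k (t = 1 of segment k).
# Rows where the derivative is degenerate are NA; the caller decides on a
# fallback (the evolution step falls back to the neighbor chord direction).
.controlPointNormals <- function(spline) {
  n <- nSegments(spline)
  out <- matrix(NA_real_, n, 2L)
  tgs <- matrix(NA_real_, n, 2L)
  for (k in seq_len(n)) {
    fr <- tryCatch(splineTangentNormal(spline, k, 1), ccsDegenerateGeometry = function(e) NULL)
    if (!is.null(fr)) {
      out[k, ] <- fr$normal
      tgs[k, ] <- fr$tangent
    }
  }
  list(normal = out, tangent = tgs)
}

#' Sample a dense closed polyline from a spline
#'
#' Visits all segments at uniform parameter steps t = 1/k, 2/k, ..., 1
#' (k = \code{pointsPerSegment}); joints are therefore included exactly once
#' and \code{pointsPerSegment = 1} returns exactly the control points, each
#' segment contributing its end point. The polyline is an implicitly closed
#' ring (last point connects back to the first).
#'
#' @inheritParams evalSpline
#' @param pointsPerSegment samples per segment, >= 1.
#' @return (n * pointsPerSegment) x 2 matrix of (x, y).
#' @export
samplePolyline <- function(spline, pointsPerSegment) {
  k <- pointsPerSegment
  if (length(k) != 1L || k < 1L || k != round(k))
    .stopInvalid("pointsPerSegment must be a single integer >= 1")
  tt <- seq_len(k) / k
  n <- nSegments(spline)
  out <- matrix(NA_real_, n * k, 2L)
  for (i in seq_len(n))
    out[(i - 1L) * k + seq_len(k), ] <- evalSpline(spline, i, tt)
  out
}

#' Perimeter of the densely sampled spline
#'
#' @inheritParams samplePolyline
#' @param pointsPerSegment samples per segment used for the polyline.
#' @return polyline length of the closed ring, in pixels.
#' @export
contourPerimeter <- function(spline, pointsPerSegment = 20L) {
  p <- samplePolyline(spline, pointsPerSegment)
  q <- p[c(seq_len(nrow(p))[-1L], 1L), , drop = FALSE]
  sum(sqrt(rowSums((q - p)^2)))
}

# Even-odd scanline fill of a closed polygon at integer pixel centers.
# poly: m x 2 (x, y) ring, implicitly closed. Returns an integer 0/255 mask.
.fillPolygon <- function(poly, nrowImg, ncolImg) {
  mask <- matrix(0L, nrowImg, ncolImg)
  m <- nrow(poly)
  x1 <- poly[, 1L]; y1 <- poly[, 2L]
  nxt <- .cycNext(m)
  x2 <- x1[nxt]; y2 <- y1[nxt]
  keep <- y1 != y2
  if (!any(keep)) return(mask)
  x1 <- x1[keep]; y1 <- y1[keep]; x2 <- x2[keep]; y2 <- y2[keep]
  ylo <- max(0L, floor(min(y1, y2)))
  yhi <- min(nrowImg - 1L, ceiling(max(y1, y2)))
  if (ylo > yhi) return(mask)
  for (yy in ylo:yhi) {
    cr <- (y1 <= yy) != (y2 <= yy)   # half-open rule in y
    if (!any(cr)) next
    xs <- sort(x1[cr] + (yy - y1[cr]) * (x2[cr] - x1[cr]) / (y2[cr] - y1[cr]))
    nx <- length(xs)
    if (nx %% 2L != 0L) next  # numerically degenerate scanline; boundary overlay covers it
    for (j in seq(1L, nx, by = 2L)) {
      a <- ceiling(xs[j] - 1e-9)
      b <- ceiling(xs[j + 1L] - 1e-9) - 1L
      a <- max(a, 0L); b <- min(b, ncolImg - 1L)
      if (a <= b) mask[yy + 1L, (a:b) + 1L] <- 255L
    }
  }
  mask
}

#' Rasterize the region enclosed by a spline
#'
#' Fills the region enclosed by the densely sampled polyline of the spline
#' (even-odd rule at pixel centers); pixels under the boundary itself are
#' also set to foreground. Foreground is 255, background 0, matching the
#' label-image convention used throughout.
#'
#' @inheritParams evalSpline
#' @param dim image dimensions c(nrow, ncol) (i.e. c(height, width)).
#' @param pointsPerSegment polyline density; the default adapts to segment
#'   chord length so rasterization error stays well below a pixel.
#' @return integer matrix of 0/255.
#' @export
contourToMask <- function(spline, dim, pointsPerSegment = NULL) {
  if (length(dim) != 2L)
    .stopInvalid("dim must be c(nrow, ncol)")
  H <- as.integer(dim[1L]); W <- as.integer(dim[2L])
  if (is.null(pointsPerSegment)) {
    pts <- spline@points
    chords <- sqrt(rowSums((pts - pts[.cycPrev(nrow(pts)), , drop = FALSE])^2))
    pointsPerSegment <- max(8L, ceiling(2 * max(chords, 1)))
  }
  poly <- samplePolyline(spline, pointsPerSegment)
  mask <- .fillPolygon(poly, H, W)
  rp <- round(poly)
  ok <- rp[, 1L] >= 0 & rp[, 1L] <= W - 1L & rp[, 2L] >= 0 & rp[, 2L] <= H - 1L
  if (any(ok))
    mask[cbind(rp[ok, 2L] + 1L, rp[ok, 1L] + 1L)] <- 255L
  if (!any(mask > 0L))
    warning("contour lies fully outside the image; returning an empty mask")
  mask
}

#' Boundary pixels of a binary mask
#'
#' Returns the inner boundary: foreground pixels with at least one
#' background pixel among their 8 neighbors (pixels beyond the image border
#' count as background). Coordinates are 0-based (x, y).
#'
#' @param mask matrix; any value > 0 is foreground.
#' @return m x 2 matrix of boundary pixel coordinates.
#' @export
maskBoundary <- function(mask) {
  m <- mask > 0
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[seq_len(H) + 1L, seq_len(W) + 1L] <- m
  bgAdj <- matrix(FALSE, H, W)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    bgAdj <- bgAdj | !pad[seq_len(H) + 1L + dy, seq_len(W) + 1L + dx]
  }
  idx <- which(m & bgAdj, arr.ind = TRUE)
  cbind(x = idx[, 2L] - 1L, y = idx[, 1L] - 1L)
}
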