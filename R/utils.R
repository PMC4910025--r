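# Internal helpers shared across modules.

# Signed area (shoelace) of a ring given as an n x 2 matrix of (x, y).
# Positive sign is the package's "counterclockwise" orientation; with the
# image convention (x = column, y = row increasing downward) a positive ring
# appears clockwise on screen, but all normal conventions are derived from
# the sign of this quantity, never from the display.
.signedArea <- function(pts) {
  x <- pts[, 1L]
  y <- pts[, 2L]
  xn <- c(x[-1L], x[1L])
  yn <- c(y[-1L], y[1L])
  0.5 * sum(x * yn - xn * y)
}

# Round half away from zero (used for the median of an even number of
# integer offsets; ties move away from the strip center).
.roundHalfAway <- function(v) {
  sign(v) * floor(abs(v) + 0.5)
}

# Bilinear interpolation at continuous pixel coordinates.
# Convention: pixel centers at integer coordinates, 0-based; x = column,
# y = row, origin top-left, so image[y + 1, x + 1] is the pixel value.
# Coordinates outside the image are clamped to the border (edge padding).
.bilinear <- function(image, x, y) {
  W <- ncol(image)
  H <- nrow(image)
  xc <- pmin(pmax(x, 0), W - 1L)
  yc <- pmin(pmax(y, 0), H - 1L)
  x0 <- floor(xc)
  y0 <- floor(yc)
  x1 <- pmin(x0 + 1, W - 1L)
  y1 <- pmin(y0 + 1, H - 1L)
  fx <- xc - x0
  fy <- yc - y0
  # column-major linear indices
  v00 <- image[y0 + 1 + x0 * H]
  v01 <- image[y0 + 1 + x1 * H]
  v10 <- image[y1 + 1 + x0 * H]
  v11 <- image[y1 + 1 + x1 * H]
  v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
    v10 * (1 - fx) * fy + v11 * fx * fy
}

# Cyclic successor / predecessor index vectors for a ring of length n.
.cycNext <- function(n) c(seq_len(n)[-1L], 1L)
.cycPrev <- function(n) c(n, seq_len(n - 1L))

.stopInvalid <- function(msg) {
  stop(errorCondition(msg, class = c("ccsInvalidInput", "error")))
}

.stopCollapse <- function(msg) {
  stop(errorCondition(msg, class = c("ccsCollapseError", "error")))
}

.stopDegenerate <- function(msg) {
  stop(errorCondition(msg, class = c("ccsDegenerateGeometry", "error")))
}
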