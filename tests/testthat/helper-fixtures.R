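# Fixtures and independent oracles, built in code.

# Ring of n points on a circle (0-based pixel coordinates).
circleRing <- function(n, r, cx = 100, cy = 100, phase = 0) {
  th <- 2 * pi * (seq_len(n) - 1) / n + phase
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# Binary disk image: inside value `fg`, outside `bg`; pixel centers 0-based.
diskImage <- function(r, size = 200, cx = 99, cy = 99, fg = 200, bg = 20) {
  x <- matrix(rep(0:(size - 1), times = size), size, size, byrow = TRUE)
  y <- matrix(rep(0:(size - 1), times = size), size, size)
  ifelse((x - cx)^2 + (y - cy)^2 <= r^2, fg, bg)
}

diskLabel <- function(r, size = 200, cx = 99, cy = 99) {
  diskImage(r, size, cx, cy, fg = 255, bg = 0)
}

# Radially textured image: gray value = f(distance from center). Used to
# plant a joint radial shift that both evolution terms must agree on.
radialImage <- function(f, size = 200, cx = 99, cy = 99) {
  x <- matrix(rep(0:(size - 1), times = size), size, size, byrow = TRUE)
  y <- matrix(rep(0:(size - 1), times = size), size, size)
  matrix(f(sqrt((x - cx)^2 + (y - cy)^2)), size, size)
}

# ---- independent oracles -------------------------------------------------

# Generic dense solve of the joint-derivative system, built literally from
# the three row patterns of the cyclic equation set (first row, interior
# rows, last row), independent of the package's solver construction.
oracleSplineDerivs <- function(p) {
  n <- length(p)
  A <- matrix(0, n, n)
  b <- numeric(n)
  A[1, 1] <- 4; A[1, 2] <- 1; A[1, n] <- A[1, n] + 1
  b[1] <- 3 * p[2] - 3 * p[n]
  if (n > 2) for (i in 2:(n - 1)) {
    A[i, i - 1] <- 1; A[i, i] <- 4; A[i, i + 1] <- 1
    b[i] <- 3 * p[i + 1] - 3 * p[i - 1]
  }
  A[n, 1] <- A[n, 1] + 1; A[n, n - 1] <- A[n, n - 1] + 1; A[n, n] <- 4
  b[n] <- 3 * p[1] - 3 * p[n - 1]
  solve(A, b)
}

# Coefficients of segment i from the end-point / end-derivative conditions.
oracleSegmentCoef <- function(p, d, i) {
  n <- length(p)
  i0 <- if (i == 1) n else i - 1
  c(p[i0], d[i0], 3 * p[i] - d[i] - 2 * d[i0] - 3 * p[i0],
    d[i] + d[i0] + 2 * p[i0] - 2 * p[i])
}

# O(n^2) double-loop Hausdorff distance.
oracleHausdorff <- function(a, b) {
  h <- function(A, B) {
    max(apply(A, 1, function(p) min(sqrt((B[, 1] - p[1])^2 + (B[, 2] - p[2])^2))))
  }
  max(h(a, b), h(b, a))
}

# Brute-force even-odd point-in-polygon scan over every pixel center
# (ray cast to the right; half-open rule in y, strict in x).
oraclePolygonMask <- function(poly, nrowImg, ncolImg) {
  m <- nrow(poly)
  nxt <- c(2:m, 1)
  mask <- matrix(0L, nrowImg, ncolImg)
  for (py in 0:(nrowImg - 1)) for (px in 0:(ncolImg - 1)) {
    cnt <- 0L
    for (e in seq_len(m)) {
      y1 <- poly[e, 2]; y2 <- poly[nxt[e], 2]
      if ((y1 <= py) != (y2 <= py)) {
        xc <- poly[e, 1] + (py - y1) * (poly[nxt[e], 1] - poly[e, 1]) / (y2 - y1)
        if (xc > px) cnt <- cnt + 1L
      }
    }
    if (cnt %% 2L == 1L) mask[py + 1, px + 1] <- 255L
  }
  mask
}

# Exhaustive contrast-offset search with the documented tie rules.
oracleContrast <- function(strip, r) {
  H <- nrow(strip)
  offs <- -floor(r / 2) + 0:(r - 1)
  rowOff <- (1:H) - 1 - (H - 1) / 2
  sc <- sapply(offs, function(x) {
    i <- rowOff < x; o <- rowOff > x
    if (!any(i) || !any(o)) return(NA_real_)
    abs(mean(strip[i, ]) - mean(strip[o, ]))
  })
  ok <- is.finite(sc)
  offs <- offs[ok]; sc <- sc[ok]
  offs[order(-sc, abs(offs), offs)][1]
}

# Inner boundary pixels under the 4-neighbor background definition
# (the pixel set a Moore trace of a 4-connected region must visit).
oracleInnerBoundary4 <- function(mask) {
  m <- mask > 0
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  bg4 <- (!pad[1:H, 2:(W + 1)]) | (!pad[3:(H + 2), 2:(W + 1)]) |
         (!pad[2:(H + 1), 1:W]) | (!pad[2:(H + 1), 3:(W + 2)])
  idx <- which(m & bg4, arr.ind = TRUE)
  cbind(x = idx[, 2] - 1L, y = idx[, 1] - 1L)
}

# Full-scale phantom benchmark run used by the acceptance tests and mirrored
# by scripts/acceptance.R: initialize on the ground-truth mask of slice 41,
# propagate to slice 159, evaluate per slice and in 3-D.
runPhantomModel <- function(model, seed, slices = 41:159) {
  pr <- modelPresets(seed)[[model]]
  pv <- generatePhantom(pr$spec)
  imgs <- lapply(slices, function(k) phantomSlice(pv, k))
  truth <- lapply(slices, function(k) ifelse(truthSlice(pv, k), 255L, 0L))
  res <- suppressWarnings(runSequence(imgs, truth[[1]], pr$evolution,
                                      pr$regularizer, truth = truth,
                                      initComponent = "largest",
                                      startIndex = slices[1]))
  tstack <- array(0L, c(dim(truth[[1]]), length(slices)))
  for (k in seq_along(slices)) tstack[, , k] <- truth[[k]]
  c(summarizeRun(res, tstack), status = res@status,
    nSlices = length(res@slices))
}
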