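test_that("fitted spline interpolates its control points at segment ends", {
  sq <- ControlPolygon(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  sp <- fitClosedSpline(sq)
  pts <- controlPoints(sq)
  n <- nrow(pts)
  for (i in seq_len(n)) {
    start <- pts[if (i == 1) n else i - 1, ]
    expect_equal(as.numeric(evalSpline(sp, i, 0)), as.numeric(start),
                 tolerance = 1e-9)
    expect_equal(as.numeric(evalSpline(sp, i, 1)), as.numeric(pts[i, ]),
                 tolerance = 1e-9)
  }
})

test_that("coefficients match a generic dense solve of the cyclic system", {
  set.seed(42)
  for (n in c(3, 4, 7, 16, 33)) {
    ring <- circleRing(n, 40) + matrix(runif(2 * n, -3, 3), n, 2)
    poly <- ControlPolygon(ring, canonicalize = FALSE)
    sp <- fitClosedSpline(poly)
    p <- controlPoints(poly)
    dx <- oracleSplineDerivs(p[, 1])
    dy <- oracleSplineDerivs(p[, 2])
    for (i in seq_len(n)) {
      expect_equal(unname(sp@coefX[i, ]), oracleSegmentCoef(p[, 1], dx, i),
                   tolerance = 1e-9)
      expect_equal(unname(sp@coefY[i, ]), oracleSegmentCoef(p[, 2], dy, i),
                   tolerance = 1e-9)
    }
  }
  # mid-segment evaluation agrees with Horner on the oracle coefficients
  sq <- ControlPolygon(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  sp <- fitClosedSpline(sq)
  p <- controlPoints(sq)
  cf <- oracleSegmentCoef(p[, 1], oracleSplineDerivs(p[, 1]), 1)
  t <- 0.5
  expect_equal(evalSpline(sp, 1, t)[1, "x"],
               c(x = cf[1] + cf[2] * t + cf[3] * t^2 + cf[4] * t^3),
               tolerance = 1e-9)
})

test_that("spline is C2-continuous at every joint including the wrap", {
  set.seed(7)
  for (n in c(3, 5, 12, 64)) {
    ring <- circleRing(n, 50) + matrix(runif(2 * n, -2, 2), n, 2)
    sp <- fitClosedSpline(ControlPolygon(ring))
    nxt <- c(2:n, 1)
    for (i in seq_len(n)) {
      # first derivative: end of segment i vs start of segment i+1
      d1end <- sp@coefX[i, 2] + 2 * sp@coefX[i, 3] + 3 * sp@coefX[i, 4]
      d1sta <- sp@coefX[nxt[i], 2]
      expect_lt(abs(d1end - d1sta), 1e-6)
      # second derivative
      d2end <- 2 * sp@coefX[i, 3] + 6 * sp@coefX[i, 4]
      d2sta <- 2 * sp@coefX[nxt[i], 3]
      expect_lt(abs(d2end - d2sta), 1e-6)
      d2endY <- 2 * sp@coefY[i, 3] + 6 * sp@coefY[i, 4]
      expect_lt(abs(d2endY - 2 * sp@coefY[nxt[i], 3]), 1e-6)
    }
  }
})

test_that("degenerate ring of identical points gives a constant spline", {
  sp <- fitClosedSpline(ControlPolygon(rbind(c(5, 7), c(5, 7), c(5, 7))))
  for (t in c(0, 0.3, 1))
    expect_equal(as.numeric(evalSpline(sp, 2, t)), c(5, 7))
})

test_that("radial deviation from a circle shrinks as control points grow", {
  devs <- vapply(c(8, 16, 32, 64), function(n) {
    sp <- fitClosedSpline(ControlPolygon(circleRing(n, 60)))
    p <- samplePolyline(sp, ceiling(10000 / n))
    max(abs(sqrt(rowSums((p - 100)^2)) - 60))
  }, numeric(1))
  expect_true(all(diff(devs) < 0))
})

test_that("invalid inputs are rejected", {
  expect_error(ControlPolygon(rbind(c(0, 0), c(1, 1))), class = "ccsInvalidInput")
  expect_error(ControlPolygon(rbind(c(0, 0), c(1, NA), c(2, 0))),
               class = "ccsInvalidInput")
  sp <- fitClosedSpline(ControlPolygon(circleRing(8, 10)))
  expect_error(evalSpline(sp, 1, 1.5), class = "ccsInvalidInput")
  expect_error(evalSpline(sp, 9, 0.5), class = "ccsInvalidInput")
})

test_that("tangent and normal are unit, orthogonal and outward", {
  n <- 64
  sp <- fitClosedSpline(ControlPolygon(circleRing(n, 60)))
  th <- 2 * pi * (seq_len(n) - 1) / n
  for (k in c(1, 9, 30, n)) {
    fr <- splineTangentNormal(sp, k, 1)   # joint = control point P_k
    expect_equal(sum(fr$tangent^2), 1, tolerance = 1e-9)
    expect_equal(sum(fr$normal^2), 1, tolerance = 1e-9)
    expect_equal(sum(fr$tangent * fr$normal), 0, tolerance = 1e-12)
    radial <- c(cos(th[k]), sin(th[k]))
    ang <- acos(min(1, sum(fr$normal * radial))) * 180 / pi
    expect_lt(ang, 5)
  }
  # random rings keep the construction properties
  set.seed(11)
  ring <- circleRing(12, 30) + matrix(runif(24, -4, 4), 12, 2)
  sp2 <- fitClosedSpline(ControlPolygon(ring))
  fr <- splineTangentNormal(sp2, 5, 0.37)
  expect_equal(sum(fr$tangent * fr$normal), 0, tolerance = 1e-12)
})

test_that("normals are invariant to the stored traversal direction", {
  ring <- circleRing(16, 40)
  a <- fitClosedSpline(ControlPolygon(ring))
  # reversed input is canonicalized back to counterclockwise
  b <- fitClosedSpline(ControlPolygon(ring[c(1, 16:2), ]))
  na <- splineTangentNormal(a, 1, 1)$normal
  nb <- splineTangentNormal(b, 1, 1)$normal
  expect_equal(na, nb, tolerance = 1e-9)
})

test_that("degenerate derivative raises a degenerate-geometry error", {
  sp <- fitClosedSpline(ControlPolygon(rbind(c(5, 7), c(5, 7), c(5, 7))))
  expect_error(splineTangentNormal(sp, 1, 1), class = "ccsDegenerateGeometry")
})

test_that("polyline sampling hits control points and measures the circle", {
  n <- 64
  sp <- fitClosedSpline(ControlPolygon(circleRing(n, 60)))
  expect_equal(samplePolyline(sp, 1), controlPoints(sp), tolerance = 1e-9)
  p <- samplePolyline(sp, 20)
  expect_equal(nrow(p), n * 20)
  expect_equal(nrow(unique(round(p, 6))), n * 20)  # no duplicated joints
  expect_lt(abs(contourPerimeter(sp, 20) - 2 * pi * 60) / (2 * pi * 60), 0.01)
  mask <- contourToMask(sp, c(200, 200))
  expect_lt(abs(sum(mask > 0) - pi * 3600) / (pi * 3600), 0.02)
})

test_that("contour rasterization matches the point-in-polygon oracle", {
  tri <- ControlPolygon(rbind(c(2, 2), c(12, 3), c(6, 12)))
  sp <- fitClosedSpline(tri)
  mask <- contourToMask(sp, c(16, 16), pointsPerSegment = 40)
  poly <- samplePolyline(sp, 40)
  oracle <- oraclePolygonMask(poly, 16, 16)
  # interior agrees exactly; the implementation additionally paints the
  # boundary polyline, so it may only add pixels on the curve itself
  extra <- which(mask != oracle)
  expect_true(all(mask[oracle > 0] == 255L))
  if (length(extra)) {
    ij <- arrayInd(extra, c(16, 16))
    d <- apply(ij, 1, function(rc) {
      min(sqrt((poly[, 1] - (rc[2] - 1))^2 + (poly[, 2] - (rc[1] - 1))^2))
    })
    expect_lt(max(d), sqrt(2) / 2 + 1e-9)  # rounding radius of boundary pixels
  }
})

test_that("rasterization is invariant to the ring start index", {
  ring <- circleRing(24, 30, 50, 50)
  m1 <- contourToMask(fitClosedSpline(ControlPolygon(ring)), c(100, 100))
  m2 <- contourToMask(fitClosedSpline(ControlPolygon(ring[c(10:24, 1:9), ])),
                      c(100, 100))
  expect_identical(m1, m2)
})

test_that("contour fully outside the image warns and returns empty mask", {
  sp <- fitClosedSpline(ControlPolygon(circleRing(8, 5, 500, 500)))
  expect_warning(m <- contourToMask(sp, c(50, 50)), "outside")
  expect_equal(sum(m), 0)
})
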