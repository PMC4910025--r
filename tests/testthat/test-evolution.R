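test_that("patch sampling reproduces analytic bilinear values", {
  # constant image
  img <- matrix(100, 30, 30)
  p <- samplePatch(img, c(15, 15), c(0, -1), 5, 7)
  expect_true(all(p@pixels == 100))
  expect_equal(p@clampedFraction, 0)
  # x-coordinate ramp, normal (1,0): a 1-wide, 5-high patch reads x-2..x+2
  ramp <- matrix(rep(0:19, times = 20), 20, 20, byrow = TRUE)
  p <- samplePatch(ramp, c(10, 10), c(1, 0), 1, 5)
  expect_equal(as.numeric(p@pixels), c(8, 9, 10, 11, 12))
  # rows run from the inward side to the outward side
  expect_equal(p@pixels[1, 1], 8)   # most inward (against the normal)
  expect_equal(p@pixels[5, 1], 12)  # most outward
})

test_that("flipping the normal flips the patch rows (w = 1)", {
  set.seed(3)
  img <- matrix(runif(400) * 255, 20, 20)
  a <- samplePatch(img, c(9.3, 11.7), c(0.6, 0.8), 1, 7)
  b <- samplePatch(img, c(9.3, 11.7), -c(0.6, 0.8), 1, 7)
  expect_equal(as.numeric(b@pixels), rev(as.numeric(a@pixels)), tolerance = 1e-12)
})

test_that("out-of-image samples are clamped and counted", {
  img <- matrix(50, 20, 20)
  p <- samplePatch(img, c(0, 10), c(-1, 0), 3, 10)  # normal points off-image
  expect_gt(p@clampedFraction, 0.3)
  expect_true(all(p@pixels == 50))  # clamped to border value of constant image
})

test_that("contrast offset finds step edges and matches exhaustive search", {
  mkstrip <- function(H, w, steprow, hi = 200, lo = 20) {
    m <- matrix(lo, H, w)
    if (steprow >= 1) m[seq_len(steprow), ] <- hi
    m
  }
  for (steprow in c(12, 17, 20, 23, 28)) {
    s <- mkstrip(40, 30, steprow)
    expect_equal(contrastOffset(s, 20), oracleContrast(s, 20))
  }
  # constant strip: all candidates tie, center wins
  expect_equal(contrastOffset(matrix(5, 40, 30), 20), 0)
  # linear ramp along the normal: verify against brute force, not intuition
  rampstrip <- matrix(rep(1:40, 30), 40, 30)
  expect_equal(contrastOffset(rampstrip, 20), oracleContrast(rampstrip, 20))
  # random strips agree with the oracle
  set.seed(99)
  for (i in 1:20) {
    s <- matrix(runif(35 * 9) * 255, 35, 9)
    expect_equal(contrastOffset(s, 15), oracleContrast(s, 15))
  }
})

test_that("similarity offset recovers a planted template", {
  set.seed(5)
  ref <- matrix(runif(20 * 30) * 255, 20, 30)
  for (planted in c(-7, 0, 5, 9)) {
    strip <- matrix(runif(40 * 30) * 255, 40, 30)
    strip[planted + 10 + seq_len(20), ] <- ref  # row block at offset `planted`
    expect_equal(similarityOffset(ref, strip, 20), planted)
  }
})

test_that("degenerate similarity inputs fall back deterministically", {
  expect_equal(similarityOffset(matrix(7, 20, 30), matrix(7, 40, 30), 20), 0)
  # zero-variance reference: correlation undefined everywhere, SSD still votes
  ref <- matrix(3, 10, 5)
  set.seed(8)
  strip <- matrix(runif(20 * 5), 20, 5)
  expect_true(similarityOffset(ref, strip, 10) %in% (-5 + 0:9))
})

test_that("the median of four votes averages the middle two, half away from center", {
  expect_equal(ccseg:::.medianVote(c(2, 2, 6, 8)), 4)
  expect_equal(ccseg:::.medianVote(c(2, 3, 4, 8)), 4)   # 3.5 rounds away from 0
  expect_equal(ccseg:::.medianVote(c(-8, -4, -3, -2)), -4)
  expect_equal(ccseg:::.medianVote(c(0, 0, 0, 9)), 0)
})

test_that("offset combination is the rounded weighted mean, halves toward xd", {
  expect_equal(combineOffsets(4, 8, 0.5, 0.5), 6)
  expect_equal(combineOffsets(3, 7, 1, 0), 3)     # alpha-only limit
  expect_equal(combineOffsets(3, 7, 0, 1), 7)     # beta-only limit
  expect_equal(combineOffsets(3, 4, 0.5, 0.5), 4) # 3.5 -> toward xd = 4
  expect_equal(combineOffsets(4, 3, 0.5, 0.5), 3) # 3.5 -> toward xd = 3
  expect_error(combineOffsets(1, 2, 0, 0), class = "ccsInvalidInput")
})

test_that("contour on a static edge stays put within a pixel", {
  img <- diskImage(55)
  sp <- fitClosedSpline(ControlPolygon(circleRing(24, 55, 99, 99)))
  ev <- evolveContour(sp, img, img, EvolutionParams(30, 20, 20), details = TRUE)
  expect_lte(max(abs(ev$trace$x)), 1)
})

test_that("a growing disk pulls the contour outward by the expected amount", {
  img1 <- diskImage(55)
  img2 <- diskImage(57)
  sp <- fitClosedSpline(ControlPolygon(circleRing(24, 55, 99, 99)))
  poly <- evolveContour(sp, img1, img2, EvolutionParams(30, 20, 20))
  radial <- sqrt(rowSums((controlPoints(poly) - 99)^2)) - 55
  expect_gte(mean(radial), 1)
  expect_lte(mean(radial), 3)
})

test_that("agreeing similarity and contrast evidence moves every point by +5", {
  # radial texture with a sharp edge; next slice shifts the whole profile
  # outward by 5 px, so template match and contrast split vote identically
  f1 <- function(d) ifelse(d <= 50, 180 + 40 * sin(d / 2), 15)
  f2 <- function(d) f1(d - 5)
  img1 <- radialImage(f1)
  img2 <- radialImage(f2)
  sp <- fitClosedSpline(ControlPolygon(circleRing(24, 50, 99, 99)))
  ev <- evolveContour(sp, img1, img2, EvolutionParams(20, 16, 20), details = TRUE)
  expect_true(all(ev$trace$x == 5))
})

test_that("evolution is translation-equivariant and lattice-bounded", {
  set.seed(21)
  base <- diskImage(30, size = 120, cx = 59, cy = 59) +
    matrix(runif(120 * 120) * 30, 120, 120)
  nxt <- diskImage(32, size = 120, cx = 59, cy = 59) +
    matrix(runif(120 * 120) * 30, 120, 120)
  shift <- c(7, -5)
  shiftImg <- function(im, s) {
    H <- nrow(im); W <- ncol(im)
    out <- matrix(0, H, W)
    src <- expand.grid(y = 1:H, x = 1:W)
    ys <- src$y - s[2]; xs <- src$x - s[1]
    ok <- ys >= 1 & ys <= H & xs >= 1 & xs <= W
    out[cbind(src$y[ok], src$x[ok])] <- im[cbind(ys[ok], xs[ok])]
    out
  }
  params <- EvolutionParams(16, 12, 10)
  sp1 <- fitClosedSpline(ControlPolygon(circleRing(16, 30, 59, 59)))
  sp2 <- fitClosedSpline(ControlPolygon(circleRing(16, 30, 59 + shift[1], 59 + shift[2])))
  p1 <- controlPoints(evolveContour(sp1, base, nxt, params))
  p2 <- controlPoints(evolveContour(sp2, shiftImg(base, shift), shiftImg(nxt, shift), params))
  expect_equal(p2, p1 + rep(1, 16) %o% shift, tolerance = 1e-9)
  # per-point offsets stay on the candidate lattice
  ev <- evolveContour(sp1, base, nxt, params, details = TRUE)
  lattice <- -floor(10 / 2) + 0:9
  expect_true(all(ev$trace$x %in% lattice))
  # determinism: identical inputs give identical outputs
  again <- evolveContour(sp1, base, nxt, params)
  expect_identical(controlPoints(again), p1)
})

test_that("border-clamped points keep their position with a warning", {
  img <- diskImage(20, size = 50, cx = 5, cy = 24)  # disk hugs the left border
  sp <- fitClosedSpline(ControlPolygon(circleRing(12, 20, 5, 24)))
  expect_warning(
    ev <- evolveContour(sp, img, img, EvolutionParams(20, 16, 10), details = TRUE),
    "unreliable")
  moved <- controlPoints(ev$polygon) - controlPoints(sp)
  expect_true(all(abs(moved[ev$trace$clamped, ]) < 1e-12))
})
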