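# Control-point evolution between neighboring slices.

#' Construct evolution parameters
#'
#' @param w,h patch width (along tangent) and height (along normal), pixels.
#' @param r sliding range: number of candidate integer offsets.
#' @param alpha weight of the patch-similarity optimum x_s.
#' @param beta weight of the inner/outer contrast optimum x_d.
#' @return an \linkS4class{EvolutionParams}.
#' @examples
#' EvolutionParams(30, 20, 20)          # the dense-phantom setting
#' EvolutionParams(80, 40, 20)          # the sparse-phantom setting
#' @export
EvolutionParams <- function(w, h, r, alpha = 0.5, beta = 0.5) {
  new("EvolutionParams", w = as.numeric(w), h = as.numeric(h),
      r = as.numeric(r), alpha = as.numeric(alpha), beta = as.numeric(beta))
}

setMethod("show", "EvolutionParams", function(object) {
  cat(sprintf("EvolutionParams: w=%g h=%g r=%g alpha=%g beta=%g\n",
              object@w, object@h, object@r, object@alpha, object@beta))
})

# The candidate offset lattice for sliding range r: exactly r integers,
# symmetric about the current position, positive = outward.
.offsetLattice <- function(r) {
  -floor(r / 2) + seq_len(r) - 1
}

#' Sample a gray-level patch in a point's local frame
#'
#' Bilinear interpolation on a w x h grid of unit-spaced sample points
#' centered at \code{center}: rows step along \code{normal} (row 1 = most
#' inward, i.e. against the outward normal), columns along the tangent
#' obtained by rotating the normal back by 90 degrees. Out-of-image samples
#' are clamped to the border value and counted in \code{clampedFraction}.
#'
#' @param image numeric matrix (gray image, matrix rows = image rows).
#' @param center length-2 (x, y) point, 0-based pixel coordinates.
#' @param normal length-2 unit outward normal.
#' @param w,h patch width and height in pixels.
#' @return a \linkS4class{Patch}.
#' @export
samplePatch <- function(image, center, normal, w, h) {
  if (w < 1L || h < 1L)
    .stopInvalid("patch width and height must be >= 1")
  tangent <- c(-normal[2L], normal[1L])
  u <- (seq_len(h) - 1) - (h - 1) / 2  # along normal
  v <- (seq_len(w) - 1) - (w - 1) / 2  # along tangent
  X <- center[1L] + outer(u * normal[1L], v * tangent[1L], "+")
  Y <- center[2L] + outer(u * normal[2L], v * tangent[2L], "+")
  outOf <- X < 0 | X > ncol(image) - 1L | Y < 0 | Y > nrow(image) - 1L
  pix <- matrix(.bilinear(image, as.vector(X), as.vector(Y)), h, w)
  new("Patch", pixels = pix, center = as.numeric(center),
      normal = as.numeric(normal), clampedFraction = mean(outOf))
}

setMethod("show", "Patch", function(object) {
  cat(sprintf("Patch %d x %d at (%.1f, %.1f), %.0f%% border-clamped\n",
              nrow(object@pixels), ncol(object@pixels),
              object@center[1L], object@center[2L],
              100 * object@clampedFraction))
})

.patchPixels <- function(p) {
  if (is(p, "Patch")) p@pixels else as.matrix(p)
}

# Deterministic argmax over the offset lattice: highest score first, then
# smallest |offset|, then inward (more negative). Candidates with
# non-finite score are excluded; returns NA if none remain.
.pickOffset <- function(offsets, score) {
  ok <- is.finite(score)
  if (!any(ok)) return(NA_integer_)
  o <- offsets[ok]; s <- score[ok]
  o[order(-s, abs(o), o)][1L]
}

#' Contrast-optimal offset along the normal
#'
#' Splits the strip (sampled on the next slice with height h + r) by the
#' line through the moving point perpendicular to the normal into an inward
#' part and an outward part, and returns the candidate offset maximizing
#' the absolute difference of the two mean gray values. All strip rows on
#' each side of the split enter the means. Ties are broken toward the
#' smallest absolute offset, then inward.
#'
#' @param strip a \linkS4class{Patch} (or matrix) of height h + r.
#' @param r the sliding range.
#' @return the integer offset x_d (0 = current position, positive = outward).
#' @export
contrastOffset <- function(strip, r) {
  pix <- .patchPixels(strip)
  H <- nrow(pix)
  if (H <= r)
    .stopInvalid("strip height must exceed the sliding range r")
  offsets <- .offsetLattice(r)
  rowOff <- (seq_len(H) - 1) - (H - 1) / 2
  rs <- rowSums(pix)
  npc <- ncol(pix)
  score <- vapply(offsets, function(x) {
    inn <- rowOff < x
    out <- rowOff > x
    if (!any(inn) || !any(out)) return(NA_real_)  # degenerate split excluded
    abs(sum(rs[inn]) / (sum(inn) * npc) - sum(rs[out]) / (sum(out) * npc))
  }, numeric(1L))
  .pickOffset(offsets, score)
}

#' Similarity-optimal offset along the normal
#'
#' Slides an h x w window through the strip over all candidate offsets and
#' scores each position against the reference patch from the current slice
#' with four measures: negative sum of squared differences, covariance,
#' Pearson correlation, and the cosine of the angle between the flattened
#' windows. Each measure votes for its best offset (ties toward the center,
#' then inward); x_s is the median of the four votes, the mean of the two
#' middle votes rounded half away from the center. Candidates where a
#' measure is undefined (zero-variance window for the correlation, zero
#' norm for the cosine) are excluded; a measure with no defined candidate
#' falls back to the SSD vote.
#'
#' @param reference h x w \linkS4class{Patch} (or matrix) from the current slice.
#' @param strip (h + r) x w \linkS4class{Patch} (or matrix) from the next slice.
#' @param r the sliding range.
#' @return the integer offset x_s.
#' @export
similarityOffset <- function(reference, strip, r) {
  ref <- .patchPixels(reference)
  pix <- .patchPixels(strip)
  h <- nrow(ref)
  if (nrow(pix) != h + r || ncol(pix) != ncol(ref))
    .stopInvalid("strip must be (h + r) x w for an h x w reference")
  offsets <- .offsetLattice(r)
  refv <- as.vector(ref)
  nref <- length(refv)
  refC <- refv - mean(refv)
  refSd <- sqrt(sum(refC^2))
  refNorm <- sqrt(sum(refv^2))
  ssd <- cv <- cr <- cs <- rep(NA_real_, r)
  for (j in seq_len(r)) {
    wv <- as.vector(pix[(j - 1L) + seq_len(h), , drop = FALSE])
    d <- wv - refv
    ssd[j] <- -sum(d * d)
    wC <- wv - mean(wv)
    wSd <- sqrt(sum(wC^2))
    if (nref > 1L)
      cv[j] <- sum(wC * refC) / (nref - 1L)
    if (wSd > 0 && refSd > 0)
      cr[j] <- sum(wC * refC) / (wSd * refSd)
    wNorm <- sqrt(sum(wv^2))
    if (wNorm > 0 && refNorm > 0)
      cs[j] <- sum(wv * refv) / (wNorm * refNorm)
  }
  v1 <- .pickOffset(offsets, ssd)
  votes <- vapply(list(cv, cr, cs), function(s) {
    v <- .pickOffset(offsets, s)
    if (is.na(v)) v1 else v
  }, numeric(1L))
  .medianVote(c(v1, votes))
}

# Median of the four measure votes: the mean of the two middle values,
# rounded to the nearest integer with halves moving away from the center.
.medianVote <- function(votes) {
  votes <- sort(votes)
  .roundHalfAway(mean(votes[2:3]))
}

#' Combine the similarity and contrast offsets
#'
#' The minimizer of \eqn{f = \alpha (x - x_s)^2 + \beta (x - x_d)^2} is the
#' weighted mean \eqn{(\alpha x_s + \beta x_d) / (\alpha + \beta)}, rounded
#' to the integer lattice; an exact half rounds toward \code{xd} (the
#' contrast evidence is the geometric one).
#'
#' @param xs,xd integer offsets from similarity and contrast.
#' @param alpha,beta non-negative weights, alpha + beta > 0.
#' @return the integer combined offset.
#' @examples
#' combineOffsets(4, 8, 0.5, 0.5)  # 6
#' @export
combineOffsets <- function(xs, xd, alpha = 0.5, beta = 0.5) {
  if (alpha + beta <= 0)
    .stopInvalid("alpha + beta must be positive")
  v <- (alpha * xs + beta * xd) / (alpha + beta)
  fl <- floor(v)
  if (abs(v - fl - 0.5) < 1e-9) {
    if (xd >= fl + 1) fl + 1 else fl
  } else {
    floor(v + 0.5)
  }
}

#' Evolve a contour onto the next slice
#'
#' For each control point \eqn{P_k} of the spline: sample the reference
#' patch on the current slice and the (h + r)-high strip on the next slice
#' around the same coordinates in the local (tangent, outward-normal)
#' frame; compute the contrast offset \eqn{x_d} and the similarity offset
#' \eqn{x_s}; combine them; and move \eqn{P_k} along its outward normal by
#' the signed result. Points whose patches are unreliable (more than half
#' border-clamped) keep their position. Where the spline derivative is
#' degenerate at a joint, the frame falls back to the chord direction of
#' the neighboring control points. The evolution is fully deterministic.
#'
#' @param spline the current slice's \linkS4class{ClosedCubicSpline}.
#' @param currentImage,nextImage gray matrices of identical dimensions.
#' @param params an \linkS4class{EvolutionParams}.
#' @param details also return the per-point evolution trace.
#' @return the evolved \linkS4class{ControlPolygon} (not yet regularized);
#'   with \code{details = TRUE}, a list with elements \code{polygon} and
#'   \code{trace} (data frame: point, xd, xs, x, clamped, flat).
#' @export
evolveContour <- function(spline, currentImage, nextImage, params,
                          details = FALSE) {
  if (!all(dim(currentImage) == dim(nextImage)))
    .stopInvalid("current and next images must have the same dimensions")
  pts <- controlPoints(spline)
  n <- nrow(pts)
  w <- params@w; h <- params@h; r <- params@r
  frames <- .controlPointNormals(spline)
  newPts <- pts
  tr <- data.frame(point = seq_len(n), xd = NA_real_, xs = NA_real_,
                   x = 0, clamped = FALSE, flat = FALSE)
  nxt <- .cycNext(n)
  prv <- .cycPrev(n)
  for (k in seq_len(n)) {
    nk <- frames$normal[k, ]
    if (anyNA(nk)) {
      # chord fallback for a degenerate joint
      ch <- pts[nxt[k], ] - pts[prv[k], ]
      len <- sqrt(sum(ch^2))
      if (len < 1e-12) next  # fully degenerate: keep the point
      tg <- ch / len
      nk <- c(tg[2L], -tg[1L])
    }
    ref <- samplePatch(currentImage, pts[k, ], nk, w, h)
    strip <- samplePatch(nextImage, pts[k, ], nk, w, h + r)
    if (ref@clampedFraction > 0.5 || strip@clampedFraction > 0.5) {
      tr$clamped[k] <- TRUE
      next
    }
    tr$flat[k] <- stats::sd(strip@pixels) < 1e-9
    xd <- contrastOffset(strip, r)
    xs <- similarityOffset(ref, strip, r)
    x <- combineOffsets(xs, xd, params@alpha, params@beta)
    tr$xd[k] <- xd; tr$xs[k] <- xs; tr$x[k] <- x
    newPts[k, ] <- pts[k, ] + x * nk
  }
  if (any(tr$clamped))
    warning(sprintf("%d control point(s) had unreliable border-clamped patches and kept their position",
                    sum(tr$clamped)))
  poly <- ControlPolygon(newPts)
  if (details) list(polygon = poly, trace = tr) else poly
}
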