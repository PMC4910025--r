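#' @import methods
NULL

#' Ordered closed ring of 2-D control points
#'
#' A \code{ControlPolygon} holds an ordered ring of \eqn{n \ge 3} control
#' points \eqn{P_1, \dots, P_n} on one slice, in continuous pixel
#' coordinates (x = column, y = row, 0-based, origin top-left). The ring is
#' implicitly closed: segment \eqn{i} runs \eqn{P_{i-1} \to P_i} with
#' \eqn{P_0 \equiv P_n}. On construction the orientation is canonicalized to
#' counterclockwise (positive shoelace area), which fixes a single outward
#' normal convention for the whole package.
#'
#' @slot points numeric matrix, n x 2, columns (x, y).
#' @export
setClass("ControlPolygon", representation(points = "matrix"))

setValidity("ControlPolygon", function(object) {
  p <- object@points
  if (!is.numeric(p) || ncol(p) != 2L)
    return("points must be a numeric matrix with 2 columns (x, y)")
  if (nrow(p) < 3L)
    return("a closed control polygon needs at least 3 points")
  if (!all(is.finite(p)))
    return("control point coordinates must be finite")
  TRUE
})

#' Closed cubic spline through a control polygon
#'
#' Per-segment cubic coefficients of a closed \eqn{C^2} interpolating
#' spline: on segment \eqn{i}, \eqn{x(t) = b_{x1} + b_{x2} t + b_{x3} t^2 +
#' b_{x4} t^3} for \eqn{t \in [0, 1]} (and likewise for \eqn{y}), with
#' \eqn{x(0) = P_{i-1}(x)} and \eqn{x(1) = P_i(x)}.
#'
#' @slot coefX numeric matrix, n x 4: b_x1..b_x4 per segment.
#' @slot coefY numeric matrix, n x 4: b_y1..b_y4 per segment.
#' @slot points the control points the spline was fitted from (n x 2).
#' @export
setClass("ClosedCubicSpline",
         representation(coefX = "matrix", coefY = "matrix", points = "matrix"))

setValidity("ClosedCubicSpline", function(object) {
  n <- nrow(object@points)
  if (nrow(object@coefX) != n || nrow(object@coefY) != n)
    return("one coefficient row per segment is required")
  if (ncol(object@coefX) != 4L || ncol(object@coefY) != 4L)
    return("each segment needs 4 coefficients per coordinate")
  TRUE
})

#' Parameters of the control-point evolution step
#'
#' \code{w} and \code{h} are the width (along the tangent) and height (along
#' the normal) of the gray-level patch sampled around each control point, in
#' pixels. \code{r} is the sliding range: the strip sampled on the next
#' slice has height \code{h + r} and the candidate offsets form the integer
#' lattice \code{-floor(r/2), ..., -floor(r/2) + r - 1} (exactly \code{r}
#' candidates, symmetric about the current position; positive = outward).
#' \code{alpha} weighs the patch-similarity optimum and \code{beta} the
#' inner/outer contrast optimum in the combined objective
#' \eqn{f = \alpha (x - x_s)^2 + \beta (x - x_d)^2}.
#'
#' @slot w,h,r integer-valued patch width, height and sliding range (pixels).
#' @slot alpha,beta non-negative weights, \code{alpha + beta > 0}.
#' @export
setClass("EvolutionParams",
         representation(w = "numeric", h = "numeric", r = "numeric",
                        alpha = "numeric", beta = "numeric"))

setValidity("EvolutionParams", function(object) {
  for (s in c("w", "h", "r")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v < 1 || v != round(v))
      return(sprintf("%s must be a single integer >= 1", s))
  }
  a <- object@alpha
  b <- object@beta
  if (a < 0 || b < 0 || a + b <= 0)
    return("alpha and beta must be non-negative with alpha + beta > 0")
  TRUE
})

#' Rectangular gray-level patch in a contour point's local frame
#'
#' Pixels are sampled by bilinear interpolation on a unit-spaced grid in the
#' (tangent, normal) frame of a contour point: rows step along the normal
#' (row 1 = most inward, last row = most outward), columns along the
#' tangent. Samples falling outside the image are clamped to the border
#' value; \code{clampedFraction} records the fraction of such samples, and a
#' patch with more than 50\% clamped samples is considered unreliable.
#'
#' @slot pixels h x w numeric matrix of gray values.
#' @slot center the 2-D point the patch was sampled around.
#' @slot normal the unit normal defining the row direction.
#' @slot clampedFraction fraction of out-of-image samples.
#' @export
setClass("Patch",
         representation(pixels = "matrix", center = "numeric",
                        normal = "numeric", clampedFraction = "numeric"))

#' Parameters of the ring regularizer
#'
#' \code{T1} is the minimum allowed distance between control points whose
#' cyclic index gap is below \code{D}; offending clusters are removed.
#' \code{T2} is the maximum allowed chord between neighbors; longer gaps are
#' re-subdivided on the fitted spline.
#'
#' @slot T1,T2 distances in pixels, \code{T1 < T2}.
#' @slot D index depth (count), \code{D >= 2}.
#' @export
setClass("RegularizerParams",
         representation(T1 = "numeric", T2 = "numeric", D = "numeric"))

setValidity("RegularizerParams", function(object) {
  if (object@T1 >= object@T2) return("T1 must be < T2")
  if (object@D < 2 || object@D != round(object@D)) return("D must be an integer >= 2")
  TRUE
})

#' Specification of a random-particle phantom volume
#'
#' Describes the simulated test volume: a bright-particle field that is
#' denser inside a spherical "nucleus" than outside. \code{shape} is
#' (rows y, columns x, slices z); \code{center} and \code{radius} define the
#' sphere in 1-based voxel indices (slice numbering starts at 1).
#' \code{pO} and \code{pB} are the per-voxel probabilities of seeding a
#' particle inside and outside the sphere; each particle is a solid 3-D ball
#' with radius uniform in \code{particleRadius} and gray value uniform
#' integer in \code{particleGray}, composited by per-voxel maximum over a
#' zero background.
#'
#' @slot shape integer length-3 (ny, nx, nz).
#' @slot center numeric length-3 sphere center, 1-based voxel indices (x, y, z).
#' @slot radius sphere radius in voxels.
#' @slot pO,pB per-voxel seeding probabilities inside / outside the sphere.
#' @slot particleRadius numeric length-2 range of ball radii (voxels).
#' @slot particleGray numeric length-2 range of gray values (integer levels).
#' @slot seed integer RNG seed; generation is fully reproducible from it.
#' @export
setClass("PhantomSpec",
         representation(shape = "numeric", center = "numeric",
                        radius = "numeric", pO = "numeric", pB = "numeric",
                        particleRadius = "numeric", particleGray = "numeric",
                        seed = "numeric"))

setValidity("PhantomSpec", function(object) {
  if (length(object@shape) != 3L || any(object@shape < 8))
    return("shape must be 3 dimensions of at least 8 voxels")
  if (object@pO < 0 || object@pO > 1 || object@pB < 0 || object@pB > 1)
    return("pO and pB must be probabilities in [0, 1]")
  if (object@radius + max(object@particleRadius) >= min(object@shape) / 2)
    return("sphere plus particle overhang must fit inside the volume")
  if (diff(object@particleRadius) < 0 || diff(object@particleGray) < 0)
    return("particleRadius and particleGray must be increasing ranges")
  TRUE
})

#' Simulated phantom volume with ground truth
#'
#' \code{volume} is the 8-bit gray stack; \code{mask} the ground-truth
#' nucleus mask: the analytic sphere united with the full extent of every
#' particle whose seed voxel lies inside the sphere (particles straddling
#' the boundary belong wholly to the nucleus area).
#'
#' @slot volume integer array (ny, nx, nz), gray 0..255.
#' @slot mask logical array of the same shape.
#' @slot spec the \linkS4class{PhantomSpec} it was generated from.
#' @export
setClass("PhantomVolume",
         representation(volume = "array", mask = "array", spec = "PhantomSpec"))

#' Per-slice result of a propagation run
#'
#' @slot sliceIndex position of the slice in the processed sequence.
#' @slot polygon the (regularized) \linkS4class{ControlPolygon}.
#' @slot spline the fitted \linkS4class{ClosedCubicSpline}.
#' @slot mask integer matrix 0/255, the filled contour.
#' @slot metrics named numeric (dc, hd, nhd) when ground truth was supplied,
#'   otherwise empty.
#' @slot diagnostics list: lowEvidence flag, number of border-clamped points.
#' @export
setClass("SliceResult",
         representation(sliceIndex = "numeric", polygon = "ControlPolygon",
                        spline = "ClosedCubicSpline", mask = "matrix",
                        metrics = "numeric", diagnostics = "list"))

#' Result of propagating a contour through a slice sequence
#'
#' @slot slices list of \linkS4class{SliceResult}, one per processed slice.
#' @slot status "ok" or "collapsed".
#' @slot failedSlice slice index where propagation stopped (NA when ok).
#' @slot nImages number of slices the run was asked to process (equals
#'   \code{length(slices)} unless the contour collapsed).
#' @slot evolution,regularizer the parameter objects used.
#' @export
setClass("PropagationResult",
         representation(slices = "list", status = "character",
                        failedSlice = "numeric", nImages = "numeric",
                        evolution = "EvolutionParams",
                        regularizer = "RegularizerParams"))
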