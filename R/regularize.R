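# Ring repair between evolution and re-fitting.

#' Construct regularizer parameters
#'
#' Defaults are the standard setting T1 = 10, T2 = 20, D = 4.
#'
#' @param T1 minimum inter-point distance (pixels).
#' @param T2 maximum neighbor chord (pixels); longer gaps are subdivided.
#' @param D index depth: only pairs with cyclic index gap < D are tested
#'   against T1.
#' @return a \linkS4class{RegularizerParams}.
#' @export
RegularizerParams <- function(T1 = 10, T2 = 20, D = 4) {
  new("RegularizerParams", T1 = as.numeric(T1), T2 = as.numeric(T2),
      D = as.numeric(D))
}

setMethod("show", "RegularizerParams", function(object) {
  cat(sprintf("RegularizerParams: T1=%g T2=%g D=%g\n",
              object@T1, object@T2, object@D))
})

#' Remove near-coincident control point clusters
#'
#' Scans the ring in index order; for each point the Euclidean distances to
#' its next 1..D-1 cyclic neighbors are examined, and for the first pair
#' (i, j) with distance < T1, the points i+1..j are deleted (the
#' lower-index point is kept). The scan restarts after every deletion,
#' since deletions change the cyclic index gaps; the result is the fixed
#' point where no such pair remains. Complicated evolved shapes can pinch
#' neighboring points past each other; this removal is what prevents the
#' re-fitted spline from self-intersecting there.
#'
#' @param polygon a \linkS4class{ControlPolygon}.
#' @param params a \linkS4class{RegularizerParams}.
#' @return the cleaned \linkS4class{ControlPolygon}.
#' @export
removeClosePairs <- function(polygon, params) {
  pts <- controlPoints(polygon)
  repeat {
    n <- nrow(pts)
    hit <- NULL
    for (i in seq_len(n)) {
      for (g in seq_len(params@D - 1L)) {
        j <- (i - 1L + g) %% n + 1L
        if (j == i) next
        d <- sqrt(sum((pts[i, ] - pts[j, ])^2))
        if (d < params@T1) {
          hit <- c(i, g)
          break
        }
      }
      if (!is.null(hit)) break
    }
    if (is.null(hit)) break
    drop <- (hit[1L] - 1L + seq_len(hit[2L])) %% n + 1L  # i+1 .. j (cyclic)
    if (n - length(drop) < 3L)
      .stopCollapse(sprintf(
        "contour collapse: removing a close cluster would leave %d < 3 control points",
        n - length(drop)))
    pts <- pts[-drop, , drop = FALSE]
  }
  ControlPolygon(pts, canonicalize = FALSE)
}

#' Subdivide over-long gaps on the fitted spline
#'
#' For each pair of neighboring control points whose chord exceeds T2,
#' ceiling(distance / T2) - 1 new points are inserted at even parameter
#' spacing along the corresponding segment of a spline fitted through the
#' current points, so the new points lie on the smooth curve rather than on
#' the chord. One re-check pass handles the rare case where curvature
#' leaves a subdivided gap still above T2.
#'
#' @param polygon a \linkS4class{ControlPolygon}.
#' @param params a \linkS4class{RegularizerParams}.
#' @param spline optional pre-fitted \linkS4class{ClosedCubicSpline} through
#'   exactly the points of \code{polygon}; fitted fresh when NULL.
#' @return the subdivided \linkS4class{ControlPolygon}.
#' @export
insertPoints <- function(polygon, params, spline = NULL) {
  pts <- controlPoints(polygon)
  for (pass in 1:2) {
    sp <- if (pass == 1L && !is.null(spline) &&
              isTRUE(all.equal(spline@points, pts))) spline
          else fitClosedSpline(ControlPolygon(pts, canonicalize = FALSE))
    n <- nrow(pts)
    prv <- .cycPrev(n)
    chords <- sqrt(rowSums((pts - pts[prv, , drop = FALSE])^2))  # chord of segment i
    if (all(chords <= params@T2)) break
    out <- vector("list", n)
    for (i in seq_len(n)) {
      seg <- list()
      if (chords[i] > params@T2) {
        kIns <- ceiling(chords[i] / params@T2) - 1L
        tt <- seq_len(kIns) / (kIns + 1L)
        seg <- list(evalSpline(sp, i, tt))
      }
      # segment i ends at P_i; emit inserted points then the end point
      out[[i]] <- rbind(if (length(seg)) seg[[1L]], pts[i, , drop = FALSE])
    }
    pts <- do.call(rbind, out)
  }
  ControlPolygon(pts, canonicalize = FALSE)
}

#' Regularize an evolved ring
#'
#' Convenience wrapper: \code{\link{removeClosePairs}} followed by
#' \code{\link{insertPoints}}.
#'
#' @inheritParams removeClosePairs
#' @return the repaired \linkS4class{ControlPolygon}.
#' @export
regularizePolygon <- function(polygon, params) {
  insertPoints(removeClosePairs(polygon, params), params)
}
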