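# Pipeline driver: initialize on the first slice, then evolve ->
# regularize -> re-fit through the sequence.

.asSliceList <- function(images) {
  if (is.list(images)) return(images)
  if (is.array(images) && length(dim(images)) == 3L)
    return(lapply(seq_len(dim(images)[3L]), function(k) images[, , k]))
  .stopInvalid("images must be a list of matrices or a 3-D array")
}

.sliceMetrics <- function(mask, spline, truth) {
  dc <- diceCoefficient(truth, mask)
  sr <- maskBoundary(truth)
  if (nrow(sr) == 0L)
    return(c(dc = dc, hd = NA_real_, nhd = NA_real_))
  sc <- maskBoundary(mask)
  if (nrow(sc) == 0L)
    return(c(dc = dc, hd = NA_real_, nhd = NA_real_))
  hd <- hausdorffDistance(sr, sc)
  c(dc = dc, hd = hd, nhd = hd / nrow(sr))
}

#' Propagate a contour through an image sequence
#'
#' Slice 1 of the sequence is initialized from the binary label image:
#' its boundary is traced, control points are selected and a closed cubic
#' spline fitted. For every further slice the previous spline is evolved
#' onto the new image, the ring is regularized (close-pair removal, gap
#' subdivision) and the spline re-fitted. Only the two slices being worked
#' on are accessed at any step, so the sequence can be arbitrarily long.
#' If a contour collapse occurs (fewer than 3 points would remain), the
#' run stops and the partial result is returned with
#' \code{status = "collapsed"}.
#'
#' @param images list of gray matrices (or a 3-D array), all identical in
#'   shape; processed in order.
#' @param label binary label image (0/255) matching slice 1.
#' @param evolution an \linkS4class{EvolutionParams}.
#' @param regularizer a \linkS4class{RegularizerParams}.
#' @param truth optional list / 3-D array of ground-truth masks; when given,
#'   per-slice Dice, Hausdorff and normalized Hausdorff are recorded.
#' @param targetCount number of initial control points; default
#'   \code{max(12, round(perimeter / T2))} so the initial spacing respects
#'   the regularizer.
#' @param detector control-point detector for the first slice, see
#'   \code{\link{extractControlPoints}}.
#' @param initComponent passed to \code{\link{traceBoundary}}: how to treat
#'   a label with several components.
#' @param startIndex slice number reported for the first slice (the
#'   sequence may be a window of a larger stack).
#' @return a \linkS4class{PropagationResult}.
#' @export
runSequence <- function(images, label, evolution, regularizer,
                        truth = NULL, targetCount = NULL,
                        detector = "uniform",
                        initComponent = "error",
                        startIndex = 1L) {
  images <- .asSliceList(images)
  if (length(images) < 2L)
    .stopInvalid("at least 2 slices are required")
  shp <- dim(images[[1L]])
  if (!all(vapply(images, function(im) all(dim(im) == shp), logical(1L))))
    .stopInvalid("all slices must have the same dimensions")
  if (!all(dim(label) == shp))
    .stopInvalid("label dimensions must match the slices")
  if (!is.null(truth)) {
    truth <- .asSliceList(truth)
    if (length(truth) != length(images))
      .stopInvalid("one ground-truth mask per slice is required")
  }

  ring <- traceBoundary(label, component = initComponent)
  if (nrow(ring) < 3L)
    .stopInvalid("traced boundary has fewer than 3 pixels")
  if (is.null(targetCount)) {
    steps <- sqrt(rowSums((ring[.cycNext(nrow(ring)), , drop = FALSE] - ring)^2))
    targetCount <- max(12L, round(sum(steps) / regularizer@T2))
    targetCount <- min(targetCount, nrow(ring))
  }
  poly <- extractControlPoints(ring, targetCount, detector = detector,
                               image = label)
  spline <- fitClosedSpline(poly)

  nSlices <- length(images)
  results <- vector("list", nSlices)
  status <- "ok"
  failed <- NA_real_
  makeResult <- function(k, poly, spline, diag) {
    mask <- contourToMask(spline, shp)
    metrics <- if (is.null(truth)) numeric(0)
               else .sliceMetrics(mask, spline, truth[[k]])
    new("SliceResult", sliceIndex = startIndex + k - 1, polygon = poly,
        spline = spline, mask = mask, metrics = metrics, diagnostics = diag)
  }
  results[[1L]] <- makeResult(1L, poly, spline,
                              list(lowEvidence = FALSE, nClamped = 0L))
  for (k in 2L:nSlices) {
    ev <- evolveContour(spline, images[[k - 1L]], images[[k]], evolution,
                        details = TRUE)
    polyNext <- tryCatch({
      cleaned <- removeClosePairs(ev$polygon, regularizer)
      insertPoints(cleaned, regularizer)
    }, ccsCollapseError = function(e) e)
    if (inherits(polyNext, "error")) {
      status <- "collapsed"
      failed <- startIndex + k - 1
      warning(sprintf("contour collapsed at slice %d: %s", failed,
                      conditionMessage(polyNext)))
      break
    }
    poly <- polyNext
    spline <- fitClosedSpline(poly)
    diag <- list(lowEvidence = all(ev$trace$flat | ev$trace$clamped),
                 nClamped = sum(ev$trace$clamped))
    if (diag$lowEvidence)
      warning(sprintf("slice %d offers no gray-level evidence; contour carried over",
                      startIndex + k - 1))
    results[[k]] <- makeResult(k, poly, spline, diag)
  }
  new("PropagationResult",
      slices = Filter(Negate(is.null), results),
      status = status, failedSlice = failed, nImages = nSlices,
      evolution = evolution, regularizer = regularizer)
}

setMethod("show", "PropagationResult", function(object) {
  cat(sprintf("PropagationResult: %d slice(s), status %s\n",
              length(object@slices), object@status))
  if (!is.na(object@failedSlice))
    cat(sprintf("  collapsed at slice %g\n", object@failedSlice))
})

#' @rdname PropagationResult-class
#' @export
setMethod("metricsTable", "PropagationResult", function(object) {
  rows <- lapply(object@slices, function(s) {
    m <- s@metrics
    data.frame(slice = s@sliceIndex,
               dc = if (length(m)) m[["dc"]] else NA_real_,
               hd = if (length(m)) m[["hd"]] else NA_real_,
               nhd = if (length(m)) m[["nhd"]] else NA_real_)
  })
  do.call(rbind, rows)
})

#' @rdname PropagationResult-class
#' @export
setMethod("maskStack", "PropagationResult", function(object) {
  shp <- dim(object@slices[[1L]]@mask)
  out <- array(0L, c(shp, length(object@slices)))
  for (k in seq_along(object@slices))
    out[, , k] <- object@slices[[k]]@mask
  out
})
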