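# Supervised evaluation: Dice coefficient, Hausdorff distance, and the
# perimeter-normalized Hausdorff distance.

#' Dice coefficient of two binary masks
#'
#' \eqn{\kappa = 2 |A_r \cap A_c| / (|A_r| + |A_c|)} with areas approximated
#' as pixel (or voxel) counts. Two empty masks are defined to agree
#' perfectly (1); one empty mask gives 0.
#'
#' @param truth,computed matrices or arrays of identical dimensions; any
#'   value > 0 is foreground.
#' @return the Dice coefficient in [0, 1].
#' @export
diceCoefficient <- function(truth, computed) {
  if (!all(dim(truth) == dim(computed)))
    .stopInvalid("masks must have identical dimensions")
  a <- truth > 0
  b <- computed > 0
  na <- sum(a)
  nb <- sum(b)
  if (na == 0L && nb == 0L) {
    message("both masks empty; Dice defined as 1")
    return(1)
  }
  2 * sum(a & b) / (na + nb)
}

#' Voxel-wise Dice of stacked per-slice masks
#'
#' Identical to \code{\link{diceCoefficient}} but named for its role:
#' comparing a stacked 3-D segmentation against the stacked ground truth
#' over the evaluated slice range.
#'
#' @param truthStack,computedStack 3-D arrays of identical dimensions.
#' @return the 3-D Dice coefficient.
#' @export
dice3D <- function(truthStack, computedStack) {
  diceCoefficient(truthStack, computedStack)
}

# Directed distances: for each row of A the distance to the nearest row of
# B, computed blockwise to bound memory.
.minDistTo <- function(A, B, block = 4096L) {
  nA <- nrow(A)
  b2 <- rowSums(B^2)
  out <- numeric(nA)
  for (s in seq(1L, nA, by = block)) {
    e <- min(s + block - 1L, nA)
    Ab <- A[s:e, , drop = FALSE]
    d2 <- outer(rowSums(Ab^2), b2, "+") - 2 * Ab %*% t(B)
    out[s:e] <- sqrt(pmax(apply(d2, 1L, min), 0))
  }
  out
}

#' Symmetric Hausdorff distance between two pixel sets
#'
#' \eqn{HD(S_r, S_c) = \max\{\max_{s_r} d(s_r, S_c), \max_{s_c} d(s_c, S_r)\}}
#' with Euclidean point-to-set distances.
#'
#' @param a,b m x 2 matrices of (x, y) pixel coordinates, both nonempty.
#' @return the Hausdorff distance in pixels.
#' @export
hausdorffDistance <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  if (nrow(a) == 0L || nrow(b) == 0L)
    .stopInvalid("Hausdorff distance needs two nonempty point sets")
  max(max(.minDistTo(a, b)), max(.minDistTo(b, a)))
}

#' Perimeter-normalized Hausdorff distance
#'
#' The Hausdorff distance divided by the size of the ground-truth boundary,
#' taken as its pixel count |S_r| (the discrete analogue of the perimeter,
#' consistent with areas as pixel counts). Note the asymmetry: the
#' normalizer is always the truth boundary.
#'
#' @param truthBoundary,computedBoundary m x 2 matrices of (x, y) pixels.
#' @return NHD = HD / |S_r| (dimensionless).
#' @export
normalizedHausdorff <- function(truthBoundary, computedBoundary) {
  if (nrow(truthBoundary) == 0L)
    .stopInvalid("the ground-truth boundary must be nonempty")
  hausdorffDistance(truthBoundary, computedBoundary) / nrow(truthBoundary)
}

#' Per-sequence metric summary
#'
#' Mean and standard deviation of the per-slice Dice and NHD values of a
#' propagation run, plus the 3-D Dice of the stacked masks. A collapsed run
#' produced no segmentation for its trailing slices: those slices enter the
#' Dice statistics as 0 (the empty-vs-nonempty convention) and the 3-D Dice
#' compares against empty masks there, while the Hausdorff statistics are
#' necessarily restricted to the slices that have a boundary.
#'
#' @param result a \linkS4class{PropagationResult} with per-slice metrics.
#' @param truthStack the ground-truth mask stack (3-D array) for the whole
#'   requested sequence, used for the 3-D Dice; omit to skip it.
#' @return a list: dcMean, dcSd, nhdMean, nhdSd, dcMin, nhdMax, dc3d.
#' @export
summarizeRun <- function(result, truthStack = NULL) {
  mt <- metricsTable(result)
  if (nrow(mt) == 0L || all(is.na(mt$dc)))
    .stopInvalid("the run carries no metrics; supply ground truth to runSequence")
  nExp <- result@nImages
  dc <- c(mt$dc, rep(0, nExp - nrow(mt)))  # collapsed slices segment nothing
  nhd <- mt$nhd[is.finite(mt$nhd)]
  out <- list(dcMean = mean(dc), dcSd = stats::sd(dc),
              nhdMean = mean(nhd), nhdSd = stats::sd(nhd),
              dcMin = min(dc), nhdMax = max(nhd), dc3d = NA_real_)
  if (!is.null(truthStack)) {
    ms <- maskStack(result)
    if (dim(ms)[3L] < dim(truthStack)[3L]) {
      pad <- array(0L, dim(truthStack))
      pad[, , seq_len(dim(ms)[3L])] <- ms
      ms <- pad
    }
    out$dc3d <- dice3D(truthStack, ms)
  }
  out
}
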