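# Initial contour extraction from a binary label image.

# 4-connected component labeling by vectorized frontier growth.
# Exact 4-connectivity matters here: diagonal-only contacts must separate
# components, since the boundary tracer assumes a 4-connected region.
.labelComponents4 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  lab <- matrix(0L, H, W)
  todo <- m
  cur <- 0L
  while (any(todo)) {
    cur <- cur + 1L
    comp <- matrix(FALSE, H, W)
    comp[which(todo)[1L]] <- TRUE
    frontier <- comp
    repeat {
      grow <- matrix(FALSE, H, W)
      grow[-1L, ] <- grow[-1L, ] | frontier[-H, ]
      grow[-H, ] <- grow[-H, ] | frontier[-1L, ]
      grow[, -1L] <- grow[, -1L] | frontier[, -W]
      grow[, -W] <- grow[, -W] | frontier[, -1L]
      grow <- grow & todo & !comp
      if (!any(grow)) break
      comp <- comp | grow
      frontier <- grow
    }
    lab[comp] <- cur
    todo <- todo & !comp
  }
  lab
}

# Moore-neighbor boundary trace of a single 4-connected component.
# m: logical matrix. Returns the boundary ring as 0-based (x, y), oriented
# counterclockwise (positive shoelace).
.mooreTrace <- function(m) {
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) == 1L)
    return(cbind(x = idx[1L, 2L] - 1L, y = idx[1L, 1L] - 1L))
  # start at the topmost, then leftmost foreground pixel
  r0 <- min(idx[, 1L])
  c0 <- min(idx[idx[, 1L] == r0, 2L])
  # 8-neighborhood in clockwise order starting west: W NW N NE E SE S SW
  offs <- rbind(c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
                c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  dirOf <- function(d) which(offs[, 1L] == d[1L] & offs[, 2L] == d[2L])
  start <- c(r0, c0)
  b0 <- c(r0, c0 - 1L)  # backtrack: west of start is background by choice of start
  p <- start; b <- b0
  path <- matrix(0L, 8L * nrow(idx) + 8L, 2L)
  np <- 0L
  repeat {
    np <- np + 1L
    if (np > nrow(path))
      .stopInvalid("boundary trace failed to terminate")
    path[np, ] <- p
    k0 <- dirOf(b - p)
    prev <- b
    nxt <- NULL
    for (s in seq_len(8L)) {
      d <- (k0 + s - 1L) %% 8L + 1L
      q <- p + offs[d, ]
      if (q[1L] >= 1L && q[1L] <= nrow(m) && q[2L] >= 1L && q[2L] <= ncol(m) &&
          m[q[1L], q[2L]]) {
        nxt <- q
        break
      }
      prev <- q
    }
    if (is.null(nxt)) break  # isolated pixel (cannot happen for n > 1 4-connected)
    p <- nxt
    b <- prev
    if (all(p == start) && all(b == b0)) break  # Jacob's stopping criterion
  }
  path <- path[seq_len(np), , drop = FALSE]
  ring <- cbind(x = path[, 2L] - 1L, y = path[, 1L] - 1L)
  if (nrow(ring) >= 3L && .signedArea(ring) < 0)
    ring <- ring[c(1L, rev(seq_len(nrow(ring))[-1L])), , drop = FALSE]
  ring
}

#' Trace the boundary of a binary label image
#'
#' Recovers an ordered closed pixel contour from a label image (foreground
#' 255, background 0) by Moore-neighbor tracing. The label must contain a
#' single 4-connected foreground component not touching the image border;
#' with \code{component = "largest"} additional (smaller) components are
#' dropped with a warning instead of raising an error, which is the right
#' behavior when initializing from a phantom ground-truth mask whose
#' boundary-convention can produce small satellite islands.
#'
#' @param label numeric/integer matrix; any nonzero pixel is foreground (a
#'   warning is emitted if values other than 0 and 255 occur).
#' @param component \code{"error"} (reject multiple components) or
#'   \code{"largest"} (keep the largest, warn).
#' @return m x 2 matrix of 0-based (x, y) boundary pixels, counterclockwise.
#' @export
traceBoundary <- function(label, component = c("error", "largest")) {
  component <- match.arg(component)
  if (!is.matrix(label))
    .stopInvalid("label must be a matrix")
  vals <- unique(as.vector(label))
  if (!all(vals %in% c(0, 255)))
    warning("label image has values other than {0, 255}; treating nonzero as foreground")
  m <- label > 0
  if (!any(m))
    .stopInvalid("label image has 0 foreground components")
  lab <- .labelComponents4(m)
  ncomp <- max(lab)
  if (ncomp > 1L) {
    if (component == "error")
      .stopInvalid(sprintf("label image has %d foreground components; expected exactly 1", ncomp))
    sizes <- tabulate(lab[lab > 0L], nbins = ncomp)
    keep <- which.max(sizes)
    warning(sprintf("label image has %d components; keeping the largest (%d px)",
                    ncomp, sizes[keep]))
    m <- lab == keep
  }
  if (any(m[1L, ]) || any(m[nrow(m), ]) || any(m[, 1L]) || any(m[, ncol(m)]))
    .stopInvalid("foreground touches the image border; a 1-pixel margin is required")
  .mooreTrace(m)
}

# Separable convolution with border clamping (replicate padding).
.convSep <- function(img, k) {
  n <- length(k)
  half <- (n - 1L) %/% 2L
  H <- nrow(img); W <- ncol(img)
  # rows (y direction)
  out <- matrix(0, H, W)
  for (i in seq_len(n)) {
    sh <- i - 1L - half
    rows <- pmin(pmax(seq_len(H) + sh, 1L), H)
    out <- out + k[i] * img[rows, , drop = FALSE]
  }
  img <- out
  out <- matrix(0, H, W)
  for (i in seq_len(n)) {
    sh <- i - 1L - half
    cols <- pmin(pmax(seq_len(W) + sh, 1L), W)
    out <- out + k[i] * img[, cols, drop = FALSE]
  }
  out
}

.gaussKernel <- function(sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k / sum(k)
}

# Harris corner response of an image (standard structure-tensor form,
# kappa = 0.04); returns local 3x3 maxima above a relative threshold as
# 0-based (x, y) with their response.
.harrisCorners <- function(img, sigma = 2, relThreshold = 0.01) {
  img <- img / max(1, max(img))
  sm <- .convSep(img, .gaussKernel(1))
  H <- nrow(sm); W <- ncol(sm)
  ix <- (sm[, pmin(seq_len(W) + 1L, W)] - sm[, pmax(seq_len(W) - 1L, 1L)]) / 2
  iy <- (sm[pmin(seq_len(H) + 1L, H), ] - sm[pmax(seq_len(H) - 1L, 1L), ]) / 2
  A <- .convSep(ix * ix, .gaussKernel(sigma))
  B <- .convSep(iy * iy, .gaussKernel(sigma))
  C <- .convSep(ix * iy, .gaussKernel(sigma))
  R <- A * B - C * C - 0.04 * (A + B)^2
  thr <- relThreshold * max(R)
  isMax <- R >= thr
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    rows <- pmin(pmax(seq_len(H) + dy, 1L), H)
    cols <- pmin(pmax(seq_len(W) + dx, 1L), W)
    isMax <- isMax & (R >= R[rows, cols])
  }
  idx <- which(isMax, arr.ind = TRUE)
  cbind(x = idx[, 2L] - 1L, y = idx[, 1L] - 1L, response = R[idx])
}

#' Select control points along a traced boundary
#'
#' Picks \code{targetCount} control points on an ordered boundary ring,
#' either at uniform arc-length spacing (\code{detector = "uniform"}, the
#' robust default) or by snapping Harris corner maxima of the label image to
#' the ring and topping up the ring by arc-length insertion until
#' \code{targetCount} points are present (\code{detector = "harris"}).
#' Ring order is always preserved.
#'
#' @param contour m x 2 ordered ring of boundary pixels (0-based x, y), as
#'   returned by \code{\link{traceBoundary}}.
#' @param targetCount number of control points, 3 <= targetCount <= m.
#' @param detector \code{"uniform"} or \code{"harris"}.
#' @param image the label (or gray) image; required for \code{"harris"}.
#' @return a \linkS4class{ControlPolygon}.
#' @export
extractControlPoints <- function(contour, targetCount,
                                 detector = c("uniform", "harris"),
                                 image = NULL) {
  detector <- match.arg(detector)
  m <- nrow(contour)
  if (targetCount < 3L)
    .stopInvalid("targetCount must be at least 3")
  if (m < targetCount)
    .stopInvalid(sprintf("ring has %d pixels; cannot select %d control points",
                         m, targetCount))
  if (m == targetCount)
    return(ControlPolygon(contour))
  steps <- sqrt(rowSums((contour[.cycNext(m), , drop = FALSE] - contour)^2))
  cum <- c(0, cumsum(steps))[seq_len(m)]  # arc length at each vertex
  total <- sum(steps)

  snapToRing <- function(s) {
    # nearest ring vertex by cyclic arc-length distance
    d <- abs(cum - s)
    which.min(pmin(d, total - d))
  }
  idx <- switch(detector,
    uniform = {
      targets <- total * (seq_len(targetCount) - 1L) / targetCount
      sort(unique(vapply(targets, snapToRing, integer(1L))))
    },
    harris = {
      if (is.null(image))
        .stopInvalid("detector = \"harris\" needs the label image")
      corners <- .harrisCorners(image)
      ci <- integer(0)
      if (nrow(corners) > 0L) {
        near <- apply(corners[, c("x", "y"), drop = FALSE], 1L, function(p) {
          which.min((contour[, 1L] - p[1L])^2 + (contour[, 2L] - p[2L])^2)
        })
        ord <- order(-corners[, "response"])
        ci <- unique(near[ord])
        if (length(ci) > targetCount) ci <- ci[seq_len(targetCount)]
      }
      sort(unique(ci))
    })
  # top up: repeatedly split the largest arc-length gap at its midpoint
  while (length(idx) < targetCount) {
    if (length(idx) == 0L) {
      idx <- 1L
      next
    }
    arcs <- cum[idx]
    gaps <- diff(c(arcs, arcs[1L] + total))
    g <- which.max(gaps)
    mid <- (arcs[g] + gaps[g] / 2) %% total
    cand <- snapToRing(mid)
    if (cand %in% idx) break  # ring saturated locally
    idx <- sort(c(idx, cand))
  }
  if (length(idx) < 3L)
    .stopInvalid("fewer than 3 distinct control points could be selected")
  ControlPolygon(contour[idx, , drop = FALSE])
}
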