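# Random-particle phantom volumes with analytic ground truth.

#' Construct a phantom specification
#'
#' Defaults are the standard study geometry: a 200 x 200 x 200 voxel volume
#' with a spherical nucleus of radius 60 centered at voxel (100, 100, 100)
#' (1-based), particles of radius uniform in [2, 3] and gray value uniform
#' integer in [140, 255].
#'
#' @param pO per-voxel particle-seeding probability inside the sphere.
#' @param pB per-voxel probability outside the sphere.
#' @param seed RNG seed; the generated volume is bit-reproducible from it.
#' @param shape volume dimensions (ny, nx, nz).
#' @param center sphere center, 1-based voxel indices (x, y, z).
#' @param radius sphere radius in voxels.
#' @param particleRadius,particleGray ranges for particle radius and gray.
#' @return a \linkS4class{PhantomSpec}.
#' @export
PhantomSpec <- function(pO, pB, seed = 1L, shape = c(200, 200, 200),
                        center = c(100, 100, 100), radius = 60,
                        particleRadius = c(2, 3), particleGray = c(140, 255)) {
  new("PhantomSpec", shape = as.numeric(shape), center = as.numeric(center),
      radius = as.numeric(radius), pO = as.numeric(pO), pB = as.numeric(pB),
      particleRadius = as.numeric(particleRadius),
      particleGray = as.numeric(particleGray), seed = as.numeric(seed))
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %s volume, sphere r=%g at (%s), pO=%g pB=%g, seed=%g\n",
              paste(object@shape, collapse = "x"), object@radius,
              paste(object@center, collapse = ","), object@pO, object@pB,
              object@seed))
})

# Ball template: integer offsets within the maximum particle radius, sorted
# by squared distance so each particle takes a prefix.
.ballTemplate <- function(rmax) {
  rr <- ceiling(rmax)
  g <- expand.grid(dy = -rr:rr, dx = -rr:rr, dz = -rr:rr)
  d2 <- g$dy^2 + g$dx^2 + g$dz^2
  keep <- d2 <= rmax^2
  g <- as.matrix(g[keep, ])
  d2 <- d2[keep]
  o <- order(d2)
  list(off = g[o, , drop = FALSE], d2 = d2[o])
}

#' Generate a phantom volume
#'
#' Every voxel draws an independent Bernoulli with probability \code{pO}
#' inside the sphere and \code{pB} outside (one draw per voxel, in fixed
#' column-major order: y fastest, then x, then z, so a seed fully determines
#' the volume). Each success seeds a solid 3-D ball with radius uniform in
#' the particle-radius range and gray value uniform integer in the gray
#' range, composited onto the zero background by per-voxel maximum. The
#' ground-truth nucleus mask is the analytic sphere united with the full
#' extent of every ball whose seed voxel lies inside the sphere (particles
#' straddling the boundary belong wholly to the nucleus).
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return a \linkS4class{PhantomVolume}.
#' @examples
#' pv <- generatePhantom(PhantomSpec(pO = 0.002, pB = 1e-5, seed = 7,
#'                                   shape = c(64, 64, 64),
#'                                   center = c(32, 32, 32), radius = 20))
#' dim(phantomSlice(pv, 32))
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  set.seed(spec@seed)
  dims <- as.integer(spec@shape)
  ny <- dims[1L]; nx <- dims[2L]; nz <- dims[3L]
  cx <- spec@center[1L]; cy <- spec@center[2L]; cz <- spec@center[3L]
  R2 <- spec@radius^2
  d2 <- outer(outer((seq_len(ny) - cy)^2, (seq_len(nx) - cx)^2, "+"),
              (seq_len(nz) - cz)^2, "+")
  inside <- d2 <= R2
  rm(d2)
  u <- array(stats::runif(prod(dims)), dims)
  succ <- u < ifelse(inside, spec@pO, spec@pB)
  rm(u)
  idx <- which(succ)
  rm(succ)
  centers <- arrayInd(idx, dims)
  insideSeed <- inside[idx]
  nP <- nrow(centers)
  radii <- stats::runif(nP, spec@particleRadius[1L], spec@particleRadius[2L])
  grays <- sample(seq(spec@particleGray[1L], spec@particleGray[2L]), nP,
                  replace = TRUE)
  vol <- array(0L, dims)
  mask <- inside
  tmpl <- .ballTemplate(spec@particleRadius[2L])
  nyx <- ny * nx
  for (p in seq_len(nP)) {
    ns <- findInterval(radii[p]^2, tmpl$d2)
    if (ns < 1L) next
    oy <- centers[p, 1L] + tmpl$off[seq_len(ns), 1L]
    ox <- centers[p, 2L] + tmpl$off[seq_len(ns), 2L]
    oz <- centers[p, 3L] + tmpl$off[seq_len(ns), 3L]
    keep <- oy >= 1L & oy <= ny & ox >= 1L & ox <= nx & oz >= 1L & oz <= nz
    li <- oy[keep] + (ox[keep] - 1L) * ny + (oz[keep] - 1L) * nyx
    vol[li] <- pmax(vol[li], grays[p])
    if (insideSeed[p]) mask[li] <- TRUE
  }
  new("PhantomVolume", volume = vol, mask = mask, spec = spec)
}

setMethod("show", "PhantomVolume", function(object) {
  cat(sprintf("PhantomVolume %s, %d nucleus voxels (ground truth), seed=%g\n",
              paste(dim(object@volume), collapse = "x"),
              sum(object@mask), object@spec@seed))
})

#' @rdname PhantomVolume-class
#' @export
setMethod("phantomSlice", "PhantomVolume", function(object, k) {
  object@volume[, , k]
})

#' @rdname PhantomVolume-class
#' @export
setMethod("truthSlice", "PhantomVolume", function(object, k) {
  object@mask[, , k]
})

#' The four standard phantom models
#'
#' Returns the four benchmark phantom settings: particle probabilities
#' (pO, pB) of (2\%, 0.001\%), (2\%, 0.1\%), (0.7\%, 0.05\%) and
#' (0.7\%, 0.1\%) on the standard geometry, each bundled with the evolution
#' parameters used for it (models 1-2: w=30, h=20, r=20; models 3-4:
#' w=80, h=40, r=20; alpha = beta = 0.5) and the standard regularizer
#' (T1=10, T2=20, D=4).
#'
#' @param seed base seed; model m uses seed + m - 1.
#' @return a list of 4 lists with elements \code{model}, \code{spec},
#'   \code{evolution}, \code{regularizer}.
#' @export
modelPresets <- function(seed = 1L) {
  probs <- list(c(0.02, 1e-5), c(0.02, 1e-3), c(0.007, 5e-4), c(0.007, 1e-3))
  evo <- list(EvolutionParams(30, 20, 20), EvolutionParams(30, 20, 20),
              EvolutionParams(80, 40, 20), EvolutionParams(80, 40, 20))
  lapply(1:4, function(m) {
    list(model = m,
         spec = PhantomSpec(pO = probs[[m]][1L], pB = probs[[m]][2L],
                            seed = seed + m - 1L),
         evolution = evo[[m]],
         regularizer = RegularizerParams())
  })
}
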