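# Along-ray surface extraction: structure entry/exit depths, the distal 90%
# isodose depth, and projections of hot-spot / under-coverage voxels onto
# the design plane. "Distal" and "proximal" are defined per ray as the last
# exit and first entry of the ray through a mask.

#' First-entry / last-exit interval of a ray through a mask
#'
#' Fixed-step sampling (step = half the smallest voxel dimension) of the
#' trilinearly interpolated mask, with bisection refinement of the two
#' boundary crossings.
#'
#' @param origin,dir ray origin and unit direction (mm); e.g. from
#'   \code{\link{planeRays}}.
#' @param mask logical 3D array on the CT grid.
#' @param ct the \linkS4class{CTVolume} supplying the geometry.
#' @return \code{c(proximal, distal)} as distances from the ray origin (mm),
#'   or \code{NULL} if the ray misses the mask.
#' @export
rayMaskInterval <- function(origin, dir, mask, ct) {
  maskNum <- array(as.numeric(mask), dim = dim(mask))
  lo <- ct@origin; hi <- ct@origin + dim(ct@voxels) * ct@spacing
  rng <- rayBoxRange(origin, dir, lo, hi)
  if (is.null(rng)) return(NULL)
  step <- min(ct@spacing) / 2
  s <- seq(rng[1], rng[2], by = step)
  P <- cbind(origin[1] + s * dir[1], origin[2] + s * dir[2],
             origin[3] + s * dir[3])
  vals <- trilinearSample(maskNum, ct@origin, ct@spacing, P, fill = 0)
  inside <- vals >= 0.5
  if (!any(inside)) return(NULL)
  a <- which(inside)[1]
  b <- which(inside)[length(which(inside))]
  refine <- function(sOut, sIn) {
    # bisection on the 0.5 level between an outside and an inside sample
    for (it in 1:25) {
      sm <- (sOut + sIn) / 2
      v <- trilinearSample(maskNum, ct@origin, ct@spacing,
                           matrix(origin + sm * dir, 1), fill = 0)
      if (v >= 0.5) sIn <- sm else sOut <- sm
      if (abs(sIn - sOut) < 0.01) break
    }
    (sOut + sIn) / 2
  }
  prox <- if (a > 1) refine(s[a - 1], s[a]) else s[a]
  dist <- if (b < length(s)) refine(s[b + 1], s[b]) else s[b]
  c(proximal = prox, distal = dist)
}

#' Distal isodose depth along a ray
#'
#' The deepest point along the ray where the trilinearly interpolated dose
#' crosses \code{level} from above, located by sampling and bisection to
#' 0.05 mm. A crossing forced only by leaving the dose grid does not count:
#' if the dose is still at or above \code{level} at the last in-grid sample,
#' the result is \code{NULL}.
#'
#' @param origin,dir ray origin and unit direction (mm).
#' @param dose a \linkS4class{DoseGrid}.
#' @param level isodose level, \% (default 90).
#' @param step sampling step, mm.
#' @return distance from the ray origin (mm), or \code{NULL} when the dose
#'   never crosses the level on the ray.
#' @export
isodoseDistalDepth <- function(origin, dir, dose, level = 90, step = 1) {
  lo <- dose@origin; hi <- dose@origin + dim(dose@dose) * dose@spacing
  rng <- rayBoxRange(origin, dir, lo, hi)
  if (is.null(rng)) return(NULL)
  s <- seq(rng[1], rng[2], by = step)
  P <- cbind(origin[1] + s * dir[1], origin[2] + s * dir[2],
             origin[3] + s * dir[3])
  vals <- trilinearSample(dose@dose, dose@origin, dose@spacing, P, fill = 0)
  above <- vals >= level
  if (!any(above)) return(NULL)
  last <- max(which(above))
  if (last == length(s)) return(NULL)  # still >= level at the grid boundary
  sHi <- s[last]; sLo <- s[last + 1]
  while (sLo - sHi > 0.05) {
    sm <- (sHi + sLo) / 2
    v <- trilinearSample(dose@dose, dose@origin, dose@spacing,
                         matrix(origin + sm * dir, 1), fill = 0)
    if (v >= level) sHi <- sm else sLo <- sm
  }
  (sHi + sLo) / 2
}

# Project voxel centers (n x 3) onto design-plane grid cells; returns a
# logical matrix over the plane.
projectVoxelsToPlane <- function(pts, plane, beam) {
  ax <- beamAxes(beam)
  out <- matrix(FALSE, length(plane@u), length(plane@v))
  if (nrow(pts) == 0) return(out)
  W <- pts - matrix(ax$source, nrow(pts), 3, byrow = TRUE)
  tAxis <- as.vector(W %*% ax$axis)
  keep <- tAxis > 0
  if (!any(keep)) return(out)
  u <- as.vector(W[keep, , drop = FALSE] %*% ax$eu) * beam@sad / tAxis[keep]
  v <- as.vector(W[keep, , drop = FALSE] %*% ax$ev) * beam@sad / tAxis[keep]
  i <- round((u - plane@u[1]) / plane@spacing) + 1
  j <- round((v - plane@v[1]) / plane@spacing) + 1
  ok <- i >= 1 & i <= length(plane@u) & j >= 1 & j <= length(plane@v)
  out[cbind(i[ok], j[ok])] <- TRUE
  out
}

#' Hot-spot region projected onto the design plane
#'
#' Voxels exceeding the hot-spot threshold inside the given mask (normally
#' BODY) are projected along their rays onto the design grid. Empty when the
#' maximum dose is below the threshold (no smoothing required below 110\%).
#'
#' @param dose a \linkS4class{DoseGrid}.
#' @param mask logical 3D array restricting the search (e.g. BODY or PTV).
#' @param plane an \linkS4class{SBTPlane}.
#' @param beam a \linkS4class{BeamSpec}.
#' @param ct the \linkS4class{CTVolume} (geometry for voxel centers).
#' @param threshold hot-spot criterion, \% (default 110).
#' @return logical matrix over the plane grid.
#' @export
hotspotRegion <- function(dose, mask, plane, beam, ct, threshold = 110) {
  flag <- dose@dose > threshold & mask
  idx <- which(flag)
  pts <- voxelCenters(dim(dose@dose), dose@spacing, dose@origin)[idx, ,
                                                                 drop = FALSE]
  projectVoxelsToPlane(pts, plane, beam)
}

#' Under-coverage region projected onto the design plane
#'
#' PTV voxels receiving less than \code{level} are projected onto the design
#' grid.
#'
#' @param dose a \linkS4class{DoseGrid}.
#' @param ptvMask logical 3D PTV mask.
#' @param plane an \linkS4class{SBTPlane}.
#' @param beam a \linkS4class{BeamSpec}.
#' @param level coverage level, \% (default 90).
#' @return logical matrix over the plane grid.
#' @export
undercoverageRegion <- function(dose, ptvMask, plane, beam, level = 90) {
  flag <- dose@dose < level & ptvMask
  idx <- which(flag)
  pts <- voxelCenters(dim(dose@dose), dose@spacing, dose@origin)[idx, ,
                                                                 drop = FALSE]
  projectVoxelsToPlane(pts, plane, beam)
}
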