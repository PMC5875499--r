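# Shift of bolus thickness (SBT). The signed thickness adjustment of a ray
# is the water-equivalent length of the gap between the distal PTV surface
# and the distal 90% isodose surface along that ray -- a line integral of
# the CET through the tissue -- divided by the CET of the bolus material.
# Positive when the 90% surface is deeper than the PTV (add bolus), negative
# when it is shallower (thin the bolus).

#' CET line integral along a ray segment
#'
#' Composite-midpoint integral of CET(z) along the ray between two distances
#' from the origin, at 0.5 mm step (HU sampled trilinearly). All sample
#' points must lie inside the CT volume.
#'
#' @param origin,dir ray origin and unit direction (mm).
#' @param ct a \linkS4class{CTVolume}.
#' @param cetTable a \linkS4class{CETTable}.
#' @param sFrom,sTo segment endpoints as distances from the origin,
#'   \code{sFrom <= sTo}.
#' @param step integration step, mm.
#' @return water-equivalent length, mm.
#' @export
cetLineIntegral <- function(origin, dir, ct, cetTable, sFrom, sTo,
                            step = 0.5) {
  stopifnot(sFrom <= sTo)
  if (sTo - sFrom == 0) return(0)
  n <- max(1L, ceiling((sTo - sFrom) / step))
  h <- (sTo - sFrom) / n
  sm <- sFrom + (seq_len(n) - 0.5) * h
  P <- cbind(origin[1] + sm * dir[1], origin[2] + sm * dir[2],
             origin[3] + sm * dir[3])
  lo <- ct@origin; hi <- ct@origin + dim(ct@voxels) * ct@spacing
  if (any(P[, 1] < lo[1] | P[, 1] > hi[1] |
          P[, 2] < lo[2] | P[, 2] > hi[2] |
          P[, 3] < lo[3] | P[, 3] > hi[3]))
    stop("integration range extends outside the CT volume", call. = FALSE)
  hu <- trilinearSample(ct@voxels, ct@origin, ct@spacing, P, fill = -1000)
  sum(cetAt(cetTable, hu)) * h
}

#' Compute the SBT grid from per-ray distal depths
#'
#' For every valid ray (one intersecting the PTV) the water-equivalent gap
#' between the distal PTV depth and the distal 90\% isodose depth is
#' integrated through the CT and divided by the bolus CET. Rays with a PTV
#' intersection but no isodose crossing are flagged and filled from the mean
#' of their valid 8-neighbors so the design can continue; non-PTV rays are
#' left at zero for the outside-PTV extrusion operator.
#'
#' @param plane an \linkS4class{SBTPlane}.
#' @param rays result of \code{\link{planeRays}} for the same plane.
#' @param ptvDepths matrix of distal PTV depths (distance from source, mm;
#'   NA where the ray misses the PTV).
#' @param isoDepths matrix of distal isodose depths (same convention).
#' @param ct a \linkS4class{CTVolume}.
#' @param cetTable a \linkS4class{CETTable}.
#' @return an \linkS4class{SBTGrid}; attribute \code{"flagged"} carries the
#'   number of PTV rays without an isodose crossing.
#' @export
computeSBT <- function(plane, rays, ptvDepths, isoDepths, ct, cetTable) {
  nu <- length(plane@u); nv <- length(plane@v)
  stopifnot(identical(dim(ptvDepths), c(nu, nv)))
  valid <- !is.na(ptvDepths)
  values <- matrix(0, nu, nv)
  flagged <- matrix(FALSE, nu, nv)
  for (j in seq_len(nv)) for (i in seq_len(nu)) {
    if (!valid[i, j]) next
    if (is.na(isoDepths[i, j])) { flagged[i, j] <- TRUE; next }
    r <- (j - 1) * nu + i
    a <- ptvDepths[i, j]; b <- isoDepths[i, j]
    wel <- cetLineIntegral(rays$source, rays$dirs[r, ], ct, cetTable,
                           min(a, b), max(a, b))
    values[i, j] <- sign(b - a) * wel / cetTable@bolusCET
  }
  # fill flagged rays from valid computed neighbors
  if (any(flagged)) {
    idx <- which(flagged, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      ni <- max(1, i - 1):min(nu, i + 1)
      nj <- max(1, j - 1):min(nv, j + 1)
      nb <- values[ni, nj][valid[ni, nj] & !flagged[ni, nj]]
      values[i, j] <- if (length(nb)) mean(nb) else 0
    }
  }
  g <- new("SBTGrid", values = values, valid = valid, plane = plane)
  attr(g, "flagged") <- sum(flagged)
  g
}

#' Apply an SBT grid to a thickness map
#'
#' \code{thickness' = max(thickness + SBT, 0)}: a physical bolus cannot be
#' thinner than zero; the number of clamped cells is reported as an
#' attribute.
#'
#' @param thickness current bolus thickness map, mm (matrix).
#' @param sbt an \linkS4class{SBTGrid} or a plain matrix of the same shape.
#' @return updated thickness matrix with attribute \code{"clamped"}.
#' @export
applySBT <- function(thickness, sbt) {
  v <- if (is(sbt, "SBTGrid")) sbt@values else sbt
  stopifnot(identical(dim(thickness), dim(v)))
  raw <- thickness + v
  out <- pmax(raw, 0)
  attr(out, "clamped") <- sum(raw < 0)
  out
}
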