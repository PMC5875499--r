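# Regional modulation operators. After the ray-line SBT estimate, five
# operators refine the thickness-shift map, in this fixed order:
#   1. hot-spot smoothing        (mode 1)
#   2. coverage smoothing        (mode 2)
#   3. irregular-surface smoothing (mode 2, gradient-thresholded)
#   4. PTV-margin adjustment     (Gaussian kernel along radial lines)
#   5. outside-PTV extrusion     (boundary value extended to the aperture)
#
# The two regional smoothing modes act on points p of a region of interest
# using Gaussian-weighted neighbors q with r_pq < SF (SF = smoothing factor,
# mm; 5 / 10 / 20 for low / medium / high):
#   mode 1:  SBT_p <- (sum_q w_q SBT_q) / (1 + sum_q w_q)
#   mode 2:  SBT_p <- (SBT_p + sum_q w_q SBT_q) / (1 + sum_q w_q)
# with w_q = exp(-r_pq^2 / (2 SF^2)). By default the q set consists of the
# points within SF of the region, excluding the region itself; an explicit
# q mask can widen it (coverage smoothing draws q from region + annulus).

sbtLike <- function(sbt) if (is(sbt, "SBTGrid")) sbt@values else sbt
rewrap <- function(sbt, values) {
  if (is(sbt, "SBTGrid")) { sbt@values <- values; sbt } else values
}

#' Regional Gaussian smoothing of an SBT map
#'
#' @param sbt an \linkS4class{SBTGrid} or plain matrix.
#' @param regionP logical matrix: the points p to adjust.
#' @param SF smoothing factor, mm (Gaussian width and neighborhood radius).
#' @param mode 1 (replace from neighbors; pulls toward 0) or 2 (blend the
#'   point's own value with its neighbors; preserves constants).
#' @param spacing grid spacing, mm (taken from the plane for an SBTGrid).
#' @param qmask optional logical matrix of allowed neighbor points; default
#'   is the SF-neighborhood of the region minus the region. A point never
#'   uses itself as a neighbor.
#' @return object of the same type as \code{sbt}, values updated on
#'   \code{regionP} only. A p with no neighbors keeps 0 (mode 1) or its own
#'   value (mode 2).
#' @export
smoothRegion <- function(sbt, regionP, SF, mode = 1, spacing = NULL,
                         qmask = NULL) {
  values <- sbtLike(sbt)
  spacing <- spacing %||% (if (is(sbt, "SBTGrid")) sbt@plane@spacing else
                             stop("spacing required for a plain matrix"))
  stopifnot(identical(dim(values), dim(regionP)), SF > 0, mode %in% c(1, 2))
  if (!any(regionP)) return(sbt)
  d <- dim(values)
  nr <- ceiling(SF / spacing)
  if (is.null(qmask)) {
    qmask <- matrix(FALSE, d[1], d[2])
    for (di in -nr:nr) for (dj in -nr:nr) {
      r <- sqrt(di^2 + dj^2) * spacing
      if (r >= SF) next
      si <- max(1, 1 - di):min(d[1], d[1] - di)
      sj <- max(1, 1 - dj):min(d[2], d[2] - dj)
      qmask[si + di, sj + dj] <- qmask[si + di, sj + dj] | regionP[si, sj]
    }
    qmask <- qmask & !regionP
  }
  num <- matrix(0, d[1], d[2])
  den <- matrix(0, d[1], d[2])
  vq <- values * qmask
  for (di in -nr:nr) for (dj in -nr:nr) {
    r <- sqrt(di^2 + dj^2) * spacing
    if (r >= SF || (di == 0 && dj == 0)) next
    w <- exp(-r^2 / (2 * SF^2))
    # target cells p receive contributions from cells at offset (di, dj)
    pi_ <- max(1, 1 - di):min(d[1], d[1] - di)
    pj <- max(1, 1 - dj):min(d[2], d[2] - dj)
    num[pi_, pj] <- num[pi_, pj] + w * vq[pi_ + di, pj + dj]
    den[pi_, pj] <- den[pi_, pj] + w * qmask[pi_ + di, pj + dj]
  }
  new_ <- if (mode == 1) num / (1 + den) else (values + num) / (1 + den)
  values[regionP] <- new_[regionP]
  rewrap(sbt, values)
}

#' Hot-spot smoothing (operator 1)
#'
#' Mode-1 smoothing on the hot-spot projection; a no-op when the region is
#' empty (maximum dose below the hot-spot criterion).
#'
#' @param sbt an \linkS4class{SBTGrid} or matrix.
#' @param hotspot logical region from \code{\link{hotspotRegion}}.
#' @param SF smoothing factor, mm (default 10).
#' @param spacing grid spacing (for plain matrices).
#' @return smoothed SBT of the same type.
#' @export
hotspotSmoothing <- function(sbt, hotspot, SF = 10, spacing = NULL) {
  if (!any(hotspot)) return(sbt)
  smoothRegion(sbt, hotspot, SF, mode = 1, spacing = spacing)
}

#' Coverage smoothing (operator 2)
#'
#' Negative SBT values inside the under-coverage region are retained; an
#' annulus of width SF around the region is smoothed with mode 2, with
#' neighbors drawn from region and annulus, so the thinning extends somewhat
#' beyond the projected under-dosed area. When every region value is
#' non-positive, all affected points end non-positive.
#'
#' @param sbt an \linkS4class{SBTGrid} or matrix.
#' @param under logical region from \code{\link{undercoverageRegion}}.
#' @param SF smoothing factor, mm (default 10).
#' @param spacing grid spacing (for plain matrices).
#' @return smoothed SBT of the same type.
#' @export
coverageSmoothing <- function(sbt, under, SF = 10, spacing = NULL) {
  if (!any(under)) return(sbt)
  sp <- spacing %||% (if (is(sbt, "SBTGrid")) sbt@plane@spacing else
                        stop("spacing required for a plain matrix"))
  annulus <- dilateMask(under, SF, sp, strict = TRUE) & !under
  if (!any(annulus)) return(sbt)
  smoothRegion(sbt, annulus, SF, mode = 2, spacing = sp,
               qmask = under | annulus)
}

#' Irregular-surface smoothing (operator 3)
#'
#' Cells whose central-difference gradient magnitude exceeds twice the mean
#' gradient magnitude are smoothed with mode 2; the criterion is re-applied
#' for up to \code{maxPasses} passes or until no cell is flagged.
#'
#' @param sbt an \linkS4class{SBTGrid} or matrix.
#' @param SF smoothing factor, mm (default 10).
#' @param maxPasses pass cap (default 3, guaranteeing termination).
#' @param spacing grid spacing (for plain matrices).
#' @return smoothed SBT of the same type; attribute \code{"passes"} records
#'   the number of passes applied.
#' @export
irregularitySmoothing <- function(sbt, SF = 10, maxPasses = 3,
                                  spacing = NULL) {
  sp <- spacing %||% (if (is(sbt, "SBTGrid")) sbt@plane@spacing else
                        stop("spacing required for a plain matrix"))
  out <- sbt
  passes <- 0L
  for (p in seq_len(maxPasses)) {
    g <- gradientMagnitude(sbtLike(out), sp)
    thr <- 2 * mean(g)
    region <- g > thr
    if (!any(region) || thr == 0) break
    out <- smoothRegion(out, region, SF, mode = 2, spacing = sp)
    passes <- passes + 1L
  }
  if (is(out, "SBTGrid")) attr(out, "passes") <- passes
  else attr(out, "passes") <- passes
  out
}

#' Central-difference gradient magnitude of a 2D map
#' @param m numeric matrix.
#' @param spacing grid spacing, mm.
#' @return matrix of |grad| values (one-sided differences at the borders).
#' @export
gradientMagnitude <- function(m, spacing) {
  d <- dim(m)
  gx <- matrix(0, d[1], d[2]); gy <- matrix(0, d[1], d[2])
  if (d[1] > 2) gx[2:(d[1] - 1), ] <- (m[3:d[1], ] - m[1:(d[1] - 2), ]) / (2 * spacing)
  if (d[1] > 1) {
    gx[1, ] <- (m[2, ] - m[1, ]) / spacing
    gx[d[1], ] <- (m[d[1], ] - m[d[1] - 1, ]) / spacing
  }
  if (d[2] > 2) gy[, 2:(d[2] - 1)] <- (m[, 3:d[2]] - m[, 1:(d[2] - 2)]) / (2 * spacing)
  if (d[2] > 1) {
    gy[, 1] <- (m[, 2] - m[, 1]) / spacing
    gy[, d[2]] <- (m[, d[2]] - m[, d[2] - 1]) / spacing
  }
  sqrt(gx^2 + gy^2)
}

#' Evaluate the margin-adjustment kernel
#' @param kernel a \linkS4class{MarginKernel}.
#' @param x radial distance(s), mm.
#' @return \code{exp(-x^2 / (2 sigma^2))}.
#' @export
kerfMA <- function(kernel, x) exp(-x^2 / (2 * kernel@sigma^2))

#' K1 of a margin kernel
#' @param kernel a \linkS4class{MarginKernel}.
#' @return \code{sigma * sqrt(-2 ln 0.01)} (mm), the distance over which the
#'   kernel rises from 0.01 to 1.
#' @export
kernelK1 <- function(kernel) kernel@k1

#' Default margin-kernel width for a beam
#'
#' The kernel width grows with both energy and applicator size;
#' \code{sqrt(energy_MeV * applicator_cm)} mm (e.g. 9 MeV with a 10 cm
#' applicator gives 9.49 mm) keeps the kernel commensurate with the 10 mm
#' border region.
#'
#' @param beam a \linkS4class{BeamSpec}.
#' @return sigma in mm.
#' @export
defaultSigma <- function(beam) sqrt(beam@energy * beam@applicator)

#' PTV-margin adjustment (operator 4)
#'
#' The PTV edge receives less scattered dose because of applicator
#' collimation; the operator therefore thins the bolus over a border region
#' (default 10 mm wide) inside the PTV projection. Along the radial line
#' from the central axis through p, m is the crossing of the border's inner
#' boundary and r_pm the distance from p to m. Then
#' \deqn{SBT_p > 0: SBT_p (1 - KerfMA(max(K1 - r_pm, 0)))}
#' \deqn{SBT_p < 0: SBT_p (1 + KerfMA(max(K1 - r_pm, 0)))}
#' so positive shifts shrink (factor in [0, 1)) and negative shifts grow in
#' magnitude (factor in (1, 2]). If the central axis lies outside the PTV
#' projection, r_pm falls back to the nearest-boundary distance (with a
#' warning).
#'
#' @param sbt an \linkS4class{SBTGrid} or matrix.
#' @param ptvProjection logical matrix: PTV projection on the plane.
#' @param kernel a \linkS4class{MarginKernel}.
#' @param spacing grid spacing (for plain matrices).
#' @return adjusted SBT of the same type.
#' @export
marginAdjustment <- function(sbt, ptvProjection, kernel, spacing = NULL) {
  values <- sbtLike(sbt)
  sp <- spacing %||% (if (is(sbt, "SBTGrid")) sbt@plane@spacing else
                        stop("spacing required for a plain matrix"))
  if (!any(ptvProjection)) return(sbt)
  d <- dim(values)
  edgeDist <- maskEdgeDistance(ptvProjection, sp)
  border <- ptvProjection & edgeDist <= kernel@borderWidth
  if (!any(border)) return(sbt)
  # grid coordinates centered on the axis point
  ic <- axisIndex(d[1]); jc <- axisIndex(d[2])
  axisInside <- ptvProjection[round(ic), round(jc)]
  hasInterior <- any(edgeDist > kernel@borderWidth)
  if (!axisInside || !hasInterior)
    warning("central axis outside the PTV projection or PTV narrower than ",
            "the border; using nearest-boundary radial fallback")
  idx <- which(border, arr.ind = TRUE)
  rpm <- numeric(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    if (!axisInside || !hasInterior) {
      rpm[r] <- kernel@borderWidth - edgeDist[i, j]
      next
    }
    rpm[r] <- radialDistanceToInnerBoundary(edgeDist, i, j, ic, jc, sp,
                                            kernel@borderWidth)
  }
  f <- kerfMA(kernel, pmax(kernel@k1 - rpm, 0))
  v <- values[idx]
  values[idx] <- ifelse(v > 0, v * (1 - f), ifelse(v < 0, v * (1 + f), 0))
  rewrap(sbt, values)
}

axisIndex <- function(n) (n + 1) / 2

# March from grid cell (i, j) toward the axis point (ic, jc) until the
# edge-distance field reaches `border` (the inner boundary of the border
# region); returns the distance traveled in mm. Falls back to the direct
# distance deficit if the march reaches the axis first.
radialDistanceToInnerBoundary <- function(edgeDist, i, j, ic, jc, sp,
                                          border) {
  dirI <- ic - i; dirJ <- jc - j
  len <- sqrt(dirI^2 + dirJ^2)
  if (len < 1e-9) return(0)
  dirI <- dirI / len; dirJ <- dirJ / len
  step <- 0.25
  sPrev <- 0; dPrev <- edgeDist[i, j]
  smax <- len
  s <- step
  coords <- function(s) c(i + dirI * s, j + dirJ * s)
  sample <- function(s) {
    c_ <- coords(s)
    bilinearSample(edgeDist, seq_len(nrow(edgeDist)), seq_len(ncol(edgeDist)),
                   c_[1], c_[2], fill = 0)
  }
  while (s <= smax + 1e-9) {
    dCur <- sample(min(s, smax))
    if (dCur >= border) {
      # linear refinement between sPrev and s
      frac <- if (dCur > dPrev) (border - dPrev) / (dCur - dPrev) else 1
      return((sPrev + frac * (min(s, smax) - sPrev)) * sp)
    }
    sPrev <- min(s, smax); dPrev <- dCur
    s <- s + step
  }
  (border - edgeDist[i, j])  # fallback: never reached the inner boundary
}

#' Outside-PTV extrusion (operator 5)
#'
#' Every grid point between the PTV projection and the expanded aperture
#' takes the SBT value at n, the first crossing of the PTV-projection
#' boundary along the segment from the point to the central-axis
#' projection; outside the expanded aperture the SBT is set to zero. The
#' operator is idempotent. If a segment never enters the PTV projection
#' (concave or off-axis projections), the nearest PTV-projection cell is
#' used instead (with a warning).
#'
#' @param sbt an \linkS4class{SBTGrid} or matrix.
#' @param ptvProjection logical matrix: PTV projection.
#' @param aperture logical matrix from \code{\link{apertureRegion}}.
#' @param spacing grid spacing (for plain matrices).
#' @return extruded SBT of the same type.
#' @export
extrudeOutside <- function(sbt, ptvProjection, aperture, spacing = NULL) {
  values <- sbtLike(sbt)
  sp <- spacing %||% (if (is(sbt, "SBTGrid")) sbt@plane@spacing else
                        stop("spacing required for a plain matrix"))
  d <- dim(values)
  if (!any(ptvProjection)) {
    warning("empty PTV projection; zeroing outside values")
    values[!ptvProjection] <- 0
    return(rewrap(sbt, values))
  }
  ic <- axisIndex(d[1]); jc <- axisIndex(d[2])
  outside <- aperture & !ptvProjection
  idx <- which(outside, arr.ind = TRUE)
  ptvIdx <- which(ptvProjection, arr.ind = TRUE)
  missed <- FALSE
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    dirI <- ic - i; dirJ <- jc - j
    len <- sqrt(dirI^2 + dirJ^2)
    found <- FALSE
    if (len > 1e-9) {
      dirI <- dirI / len; dirJ <- dirJ / len
      s <- 0.5
      while (s <= len + 1e-9) {
        ii <- as.integer(round(i + dirI * s))
        jj <- as.integer(round(j + dirJ * s))
        if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] &&
            ptvProjection[ii, jj]) {
          values[i, j] <- values[ii, jj]
          found <- TRUE
          break
        }
        s <- s + 0.5
      }
    }
    if (!found) {
      # nearest-boundary fallback
      dd <- (ptvIdx[, 1] - i)^2 + (ptvIdx[, 2] - j)^2
      k <- which.min(dd)
      values[i, j] <- values[ptvIdx[k, 1], ptvIdx[k, 2]]
      missed <- TRUE
    }
  }
  if (missed)
    warning("some segments missed the PTV projection; ",
            "nearest-boundary fallback used")
  values[!aperture & !ptvProjection] <- 0
  rewrap(sbt, values)
}
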