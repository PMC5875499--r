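# 2D gamma analysis: combined dose-difference / distance-to-agreement
# comparison of two coplanar dose distributions on a common grid, with
# global normalization.

#' 2D gamma index between two dose planes
#'
#' For each evaluation point the gamma value is the minimum over reference
#' points r within the search disk of
#' \code{sqrt((|d| / distCrit)^2 + (dDose / (doseCrit/100 * maxRef))^2)},
#' where \code{d} is the spatial offset and \code{dDose} the dose difference
#' (global normalization to the reference maximum). A point passes when
#' gamma <= 1. The search disk radius is 3 x \code{distCrit}.
#'
#' @param evalPlane,refPlane numeric matrices on the same grid (\%).
#' @param spacing grid spacing, mm.
#' @param doseCrit dose criterion, \% of the global reference maximum
#'   (default 3).
#' @param distCrit distance-to-agreement criterion, mm (default 5).
#' @return list with \code{gamma} (matrix), \code{passRate} (\% of points
#'   with gamma <= 1) and the criteria used.
#' @export
gamma2d <- function(evalPlane, refPlane, spacing, doseCrit = 3, distCrit = 5) {
  stopifnot(identical(dim(evalPlane), dim(refPlane)))
  maxRef <- max(refPlane)
  if (maxRef <= 0) stop("all-zero reference plane", call. = FALSE)
  dd <- doseCrit / 100 * maxRef
  d <- dim(refPlane)
  rmax <- 3 * distCrit
  nc <- floor(rmax / spacing)
  g2 <- matrix(Inf, d[1], d[2])
  for (di in -nc:nc) for (dj in -nc:nc) {
    r <- sqrt(di^2 + dj^2) * spacing
    if (r > rmax) next
    # reference shifted by (di, dj) compared against the evaluation plane
    ei <- max(1, 1 - di):min(d[1], d[1] - di)
    ej <- max(1, 1 - dj):min(d[2], d[2] - dj)
    diff <- evalPlane[ei, ej, drop = FALSE] -
            refPlane[ei + di, ej + dj, drop = FALSE]
    cand <- (r / distCrit)^2 + (diff / dd)^2
    g2[ei, ej] <- pmin(g2[ei, ej], cand)
  }
  g <- sqrt(g2)
  list(gamma = g, passRate = 100 * mean(g <= 1 + 1e-9),
       doseCrit = doseCrit, distCrit = distCrit)
}

#' Extract a 2D dose plane from a DoseGrid
#'
#' Convenience for gamma comparisons: an axis-aligned slice through the
#' grid.
#'
#' @param dose a \linkS4class{DoseGrid}.
#' @param axis 1, 2 or 3 (x, y, z).
#' @param index slice index along that axis.
#' @return a numeric matrix.
#' @export
dosePlane <- function(dose, axis = 2, index = NULL) {
  d <- dim(dose@dose)
  index <- index %||% ceiling(d[axis] / 2)
  switch(axis,
         dose@dose[index, , ],
         dose@dose[, index, ],
         dose@dose[, , index])
}
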