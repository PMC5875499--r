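# Bolus solid construction. The thickness map on the design grid is turned
# into a watertight triangulated solid: inner surface on the patient skin
# (ray-BODY entry points), outer surface displaced toward the source along
# each diverging ray by the local thickness, and a vertical skirt closing
# the boundary of the grid footprint.

#' Build the printable bolus solid from a thickness map
#'
#' @param thickness matrix of bolus thickness (mm, >= 0) on the design grid.
#' @param bodyMask logical 3D BODY mask on the CT grid.
#' @param plane the \linkS4class{SBTPlane} of the thickness map.
#' @param beam the \linkS4class{BeamSpec}.
#' @param ct the \linkS4class{CTVolume}.
#' @return a \linkS4class{BolusSolid}; NULL (with a warning) when the
#'   thickness is zero everywhere.
#' @export
buildSolid <- function(thickness, bodyMask, plane, beam, ct) {
  nu <- length(plane@u); nv <- length(plane@v)
  stopifnot(identical(dim(thickness), c(nu, nv)))
  if (any(thickness < 0)) stop("thickness must be >= 0", call. = FALSE)
  if (all(thickness == 0)) {
    warning("zero thickness everywhere; no solid built")
    return(NULL)
  }
  rays <- planeRays(beam, plane)
  sInner <- matrix(NA_real_, nu, nv)
  for (j in seq_len(nv)) for (i in seq_len(nu)) {
    r <- (j - 1) * nu + i
    iv <- rayMaskInterval(rays$source, rays$dirs[r, ], bodyMask, ct)
    if (is.null(iv))
      stop("no BODY entry for design grid point (", i, ", ", j, ")",
           call. = FALSE)
    sInner[i, j] <- iv["proximal"]
  }
  sOuter <- sInner - thickness  # toward the source along the ray
  idx <- function(i, j) (j - 1) * nu + i
  mk <- function(S) {
    V <- matrix(0, nu * nv, 3)
    for (j in seq_len(nv)) for (i in seq_len(nu)) {
      r <- idx(i, j)
      V[r, ] <- rays$source + S[i, j] * rays$dirs[r, ]
    }
    V
  }
  Vin <- mk(sInner)
  Vout <- mk(sOuter)
  vertices <- rbind(Vout, Vin)       # outer block first, inner offset nu*nv
  off <- nu * nv
  tris <- vector("list", 4 * (nu - 1) * (nv - 1) + 4 * (nu - 1) + 4 * (nv - 1))
  tct <- 0L
  addTri <- function(a, b, c_) {
    tct <<- tct + 1L
    tris[[tct]] <<- c(a, b, c_)
  }
  # outer (top) surface: outward normal toward the source
  for (j in seq_len(nv - 1)) for (i in seq_len(nu - 1)) {
    a <- idx(i, j); b <- idx(i + 1, j); c_ <- idx(i + 1, j + 1); e <- idx(i, j + 1)
    addTri(a, c_, b); addTri(a, e, c_)
    # inner (bottom) surface: opposite winding
    addTri(off + a, off + b, off + c_); addTri(off + a, off + c_, off + e)
  }
  # skirt: four borders of the footprint
  for (i in seq_len(nu - 1)) {
    a <- idx(i, 1); b <- idx(i + 1, 1)
    addTri(a, b, off + b); addTri(a, off + b, off + a)
    a <- idx(i, nv); b <- idx(i + 1, nv)
    addTri(a, off + b, b); addTri(a, off + a, off + b)
  }
  for (j in seq_len(nv - 1)) {
    a <- idx(1, j); b <- idx(1, j + 1)
    addTri(a, off + b, b); addTri(a, off + a, off + b)
    a <- idx(nu, j); b <- idx(nu, j + 1)
    addTri(a, b, off + b); addTri(a, off + b, off + a)
  }
  Tr <- do.call(rbind, tris[seq_len(tct)])
  solid <- new("BolusSolid", vertices = vertices, triangles = Tr,
               plane = plane, beam = beam, sInner = sInner, sOuter = sOuter,
               thickness = thickness)
  if (meshVolume(solid) < 0) solid@triangles <- Tr[, c(1, 3, 2)]
  solid
}

#' Signed mesh volume (divergence theorem)
#' @param solid a \linkS4class{BolusSolid} (or any vertices/triangles pair).
#' @return volume in mm^3 (positive for outward-oriented meshes).
#' @export
meshVolume <- function(solid) {
  V <- solid@vertices; Tr <- solid@triangles
  a <- V[Tr[, 1], , drop = FALSE]
  b <- V[Tr[, 2], , drop = FALSE]
  c_ <- V[Tr[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
      a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Watertightness check (oriented edge manifold)
#'
#' A closed orientable triangle mesh has every directed edge appearing
#' exactly once (each undirected edge shared by exactly two triangles with
#' opposite orientation).
#'
#' @param solid a \linkS4class{BolusSolid}.
#' @return TRUE/FALSE.
#' @export
isWatertight <- function(solid) {
  Tr <- solid@triangles
  e <- rbind(Tr[, c(1, 2)], Tr[, c(2, 3)], Tr[, c(3, 1)])
  keys <- paste(e[, 1], e[, 2])
  rkeys <- paste(e[, 2], e[, 1])
  !anyDuplicated(keys) && all(keys %in% rkeys)
}

#' Voxelize the bolus solid onto the CT grid
#'
#' Uses the ray-height-field construction of the solid: a voxel center is
#' inside when its fan coordinates fall in the footprint and its source
#' distance lies between the outer and inner surface distances
#' (bilinearly interpolated). Returns the mask and the HU override for
#' recalculation with the bolus in place (printed PLA images at about
#' 160 HU).
#'
#' @param solid a \linkS4class{BolusSolid} from \code{\link{buildSolid}}.
#' @param ct the \linkS4class{CTVolume}.
#' @param hu override value, HU (default 160).
#' @return list with \code{mask} (logical array), \code{hu} and \code{ct}
#'   (the CT with the override applied).
#' @export
solidToStructure <- function(solid, ct, hu = 160) {
  plane <- solid@plane; beam <- solid@beam
  lo <- ct@origin; hi <- ct@origin + dim(ct@voxels) * ct@spacing
  if (any(apply(solid@vertices, 2, min) < lo - 1e-6) ||
      any(apply(solid@vertices, 2, max) > hi + 1e-6))
    warning("solid extends outside the CT volume; clipping")
  ax <- beamAxes(beam)
  d <- dim(ct@voxels)
  centers <- voxelCenters(d, ct@spacing, ct@origin)
  W <- centers - matrix(ax$source, nrow(centers), 3, byrow = TRUE)
  tAxis <- as.vector(W %*% ax$axis)
  ok <- tAxis > 0
  s <- sqrt(rowSums(W^2))
  u <- as.vector(W %*% ax$eu) * beam@sad / tAxis
  v <- as.vector(W %*% ax$ev) * beam@sad / tAxis
  sOutI <- bilinearSample(solid@sOuter, plane@u, plane@v, u, v, fill = NA)
  sInI <- bilinearSample(solid@sInner, plane@u, plane@v, u, v, fill = NA)
  inside <- ok & !is.na(sOutI) & !is.na(sInI) & s >= sOutI & s <= sInI
  inside[is.na(inside)] <- FALSE
  mask <- array(inside, dim = d)
  newHU <- ct@voxels
  newHU[mask] <- as.integer(hu)
  list(mask = mask, hu = hu,
       ct = ctVolume(newHU, spacing = ct@spacing, origin = ct@origin))
}

#' Write the solid plus a fabrication sidecar
#'
#' Writes the binary STL and a YAML sidecar recording material, CET, HU
#' override and the print profile (layer height, infill); the print
#' parameters are metadata only.
#'
#' @param solid a \linkS4class{BolusSolid}.
#' @param path STL output path (sidecar gets extension .yaml).
#' @param profile print profile: \code{"low"}, \code{"standard"} or
#'   \code{"high"} (layer heights 0.3 / 0.2 / 0.1 mm).
#' @param cet bolus CET recorded in the sidecar.
#' @return the STL path, invisibly.
#' @export
writeBolus <- function(solid, path, profile = c("standard", "low", "high"),
                       cet = 1.119) {
  profile <- match.arg(profile)
  layer <- c(low = 0.3, standard = 0.2, high = 0.1)[[profile]]
  writeSTL(solid, path)
  yaml::write_yaml(list(material = "PLA", cet = cet, hu_override = 160,
                        print_profile = list(name = profile,
                                             layer_height_mm = layer,
                                             infill_percent = 100,
                                             infill_pattern = "linear")),
                   paste0(sub("\\.stl$", "", path), ".yaml"))
  invisible(path)
}
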