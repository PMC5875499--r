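# Beam coordinate system and divergent ray construction.
#
# Patient coordinates (x, y, z) in mm. Gantry angle g rotates the beam in
# the x-z plane: the central-axis direction is d = (sin g, 0, cos g), so at
# g = 0 the beam travels along +z. The virtual point source sits on the
# central axis at SAD mm upstream of the isocenter. The design (SBT) plane
# contains the isocenter, is perpendicular to the axis, and carries in-plane
# axes eu = (cos g, 0, -sin g) (rotated lateral) and ev = (0, 1, 0).

#' Beam axes for a BeamSpec
#' @param beam a \linkS4class{BeamSpec}.
#' @return list with unit vectors \code{axis}, \code{eu}, \code{ev} and the
#'   virtual \code{source} position (mm).
#' @export
beamAxes <- function(beam) {
  g <- beam@gantry * pi / 180
  axis <- c(sin(g), 0, cos(g))
  list(axis = axis,
       eu = c(cos(g), 0, -sin(g)),
       ev = c(0, 1, 0),
       source = beam@isocenter - beam@sad * axis)
}

#' Build the design (SBT) plane for a beam
#'
#' The grid covers the applicator projection at the isocenter plane plus a
#' margin on every side, at the requested spacing, with a grid point exactly
#' on the central axis. A 10 x 10 cm applicator with 10 mm margin and 2.5 mm
#' spacing yields a 49 x 49 grid.
#'
#' @param beam a \linkS4class{BeamSpec}.
#' @param margin extra half-extent beyond the field edge, mm (default 10,
#'   matching the outside-PTV extrusion region).
#' @param spacing grid spacing, mm (default 2.5).
#' @return an \linkS4class{SBTPlane}.
#' @export
buildSbtPlane <- function(beam, margin = 10, spacing = 2.5) {
  stopifnot(margin >= 0, spacing > 0)
  ax <- beamAxes(beam)
  half <- beam@applicator * 10 / 2 + margin
  n <- ceiling(half / spacing - 1e-9)
  coords <- (-n:n) * spacing
  new("SBTPlane", center = beam@isocenter, eu = ax$eu, ev = ax$ev,
      normal = ax$axis, spacing = spacing, u = coords, v = coords)
}

#' Physical positions of the plane grid points
#' @param plane an \linkS4class{SBTPlane}.
#' @return an n x 3 matrix (row order: u fastest), n = length(u) * length(v).
#' @export
planePoints <- function(plane) {
  nu <- length(plane@u); nv <- length(plane@v)
  U <- rep(plane@u, times = nv); V <- rep(plane@v, each = nu)
  cbind(plane@center[1] + U * plane@eu[1] + V * plane@ev[1],
        plane@center[2] + U * plane@eu[2] + V * plane@ev[2],
        plane@center[3] + U * plane@eu[3] + V * plane@ev[3])
}

#' Ray through one design-grid point
#'
#' Rays start at the virtual source and pass through their grid point,
#' diverging from the central axis everywhere except at the axis point.
#'
#' @param beam a \linkS4class{BeamSpec}.
#' @param plane an \linkS4class{SBTPlane}.
#' @param i,j 1-based grid indices into \code{plane@u}, \code{plane@v}.
#' @return a \linkS4class{Ray}.
#' @export
rayThrough <- function(beam, plane, i, j) {
  stopifnot(i >= 1, i <= length(plane@u), j >= 1, j <= length(plane@v))
  ax <- beamAxes(beam)
  p <- plane@center + plane@u[i] * plane@eu + plane@v[j] * plane@ev
  new("Ray", origin = ax$source, direction = normalize3(p - ax$source),
      planePoint = p)
}

#' All rays of a plane as matrices
#' @param beam a \linkS4class{BeamSpec}.
#' @param plane an \linkS4class{SBTPlane}.
#' @return list with \code{source} (length 3) and \code{dirs} (n x 3 unit
#'   directions, same row order as \code{\link{planePoints}}).
#' @export
planeRays <- function(beam, plane) {
  ax <- beamAxes(beam)
  P <- planePoints(plane)
  D <- P - matrix(ax$source, nrow(P), 3, byrow = TRUE)
  D <- D / sqrt(rowSums(D^2))
  list(source = ax$source, dirs = D)
}

#' Aperture region on the design plane
#'
#' Grid points inside the applicator projection at the isocenter plane,
#' expanded by \code{beyond} mm on every side.
#'
#' @param beam a \linkS4class{BeamSpec}.
#' @param plane an \linkS4class{SBTPlane}.
#' @param beyond expansion beyond the field edge, mm (default 10).
#' @return logical matrix of dim (length(u), length(v)).
#' @export
apertureRegion <- function(beam, plane, beyond = 10) {
  half <- beam@applicator * 10 / 2 + beyond
  outer(abs(plane@u) <= half + 1e-9, abs(plane@v) <= half + 1e-9, "&")
}
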