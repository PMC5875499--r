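# Broad-beam electron dose surrogate.
#
# This engine exists so the bolus-design iteration loop can run at desk
# scale with a deterministic, monotone, heterogeneity-aware dose model. It
# is a documented simplification -- a central-axis depth-dose model applied
# at the water-equivalent depth of each point, with error-function field
# edges -- and is not a replacement for a clinical Monte Carlo engine.
# Externally computed dose (e.g. from a treatment planning system) can be
# substituted per iteration through the `engine` argument of runDesign().
#
# Depth-dose parameterization per energy E (MeV), depths in mm:
#   R50  = E / 2.33 cm    (depth of 50% dose)
#   Rp   = E / 2 cm       (practical range)
#   zmax = 0.6 * R50      (depth of maximum)
#   surface dose 85%, bremsstrahlung tail 2%
# Build-up: parabola from 85% at the surface to 100% at zmax with zero slope
# at the join. Falloff: a logistic in depth, normalized to 100 at zmax, with
# its midpoint solved so that dose(R50) = 50 exactly and width
# w = (Rp - R50) / 3. Beyond the falloff the curve settles onto the 2% tail.

surrogateConstants <- list(surface = 85, tail = 2,
                           penumbraSigma0 = 2, penumbraSlope = 0.05)

.pddCache <- new.env(parent = emptyenv())

#' Depth-dose model for one beam energy
#'
#' @param energy beam energy, MeV.
#' @return a list with parameters \code{R50}, \code{Rp}, \code{zmax} (mm) and
#'   the calibrated logistic midpoint/width; pass to \code{\link{pddEval}}.
#' @export
pddModel <- function(energy) {
  key <- sprintf("%.6g", energy)
  if (!is.null(.pddCache[[key]])) return(.pddCache[[key]])
  stopifnot(energy > 0)
  R50 <- energy / 2.33 * 10
  Rp <- energy / 2 * 10
  zmax <- 0.6 * R50
  w <- (Rp - R50) / 3
  tail <- surrogateConstants$tail
  L <- function(z, z50) 1 / (1 + exp((z - z50) / w))
  f <- function(z50) tail + (100 - tail) * L(R50, z50) / L(zmax, z50) - 50
  z50 <- stats::uniroot(f, c(zmax, Rp + 20), tol = 1e-10)$root
  m <- list(energy = energy, R50 = R50, Rp = Rp, zmax = zmax, w = w,
            z50 = z50, Lzmax = L(zmax, z50))
  .pddCache[[key]] <- m
  m
}

#' Evaluate the surrogate percentage depth dose
#'
#' Continuous in depth; 100 at \code{zmax}, 50 at \code{R50} (within 0.1),
#' monotone non-increasing beyond \code{zmax} down to the 2\% tail.
#'
#' @param model a model from \code{\link{pddModel}} (or an energy in MeV).
#' @param z water-equivalent depth(s), mm (>= 0).
#' @return dose in \% of the depth-dose maximum.
#' @export
pddEval <- function(model, z) {
  if (is.numeric(model)) model <- pddModel(model)
  surface <- surrogateConstants$surface
  tail <- surrogateConstants$tail
  out <- numeric(length(z))
  up <- z <= model$zmax
  out[up] <- surface + (100 - surface) * (1 - ((model$zmax - z[up]) / model$zmax)^2)
  if (any(!up)) {
    L <- 1 / (1 + exp((z[!up] - model$z50) / model$w))
    out[!up] <- tail + (100 - tail) * L / model$Lzmax
  }
  out
}

#' Invert the surrogate depth dose on its falloff
#'
#' Depth at which the falloff crosses \code{level}, used as an analytic
#' oracle for isodose-depth extraction and for uniform-thickness solutions.
#'
#' @param model a model from \code{\link{pddModel}} (or an energy in MeV).
#' @param level dose level, \% (must lie between the tail and 100).
#' @return depth in mm (> zmax).
#' @export
pddInvert <- function(model, level) {
  if (is.numeric(model) && length(model) == 1) model <- pddModel(model)
  stopifnot(level > surrogateConstants$tail, level < 100)
  stats::uniroot(function(z) pddEval(model, z) - level,
                 c(model$zmax, model$Rp + 30 * model$w), tol = 1e-8)$root
}

# Lateral field factor: product of error-function edges of the square field,
# evaluated in isocenter-plane coordinates (u, v), with depth-dependent
# penumbra sigma(z) = 2 mm + 0.05 z.
lateralFactor <- function(u, v, zeff, halfField) {
  sg <- surrogateConstants$penumbraSigma0 +
        surrogateConstants$penumbraSlope * pmax(zeff, 0)
  s2 <- sqrt(2) * sg
  fu <- 0.5 * (erf((halfField - u) / s2) + erf((halfField + u) / s2))
  fv <- 0.5 * (erf((halfField - v) / s2) + erf((halfField + v) / s2))
  fu * fv
}

#' Compute a 3D dose grid with the broad-beam surrogate engine
#'
#' For every point the engine traces its divergent ray from the virtual
#' source, accumulates the water-equivalent depth (bolus CET path plus
#' tissue CET path from the body entry), evaluates the depth-dose model
#' there and applies the error-function field-edge factor. Dose is
#' renormalized so that the open-field maximum on the central axis is 100%.
#' Internally the beam is sampled on a fan grid (one ray per design-grid
#' point, fixed radial step) and the CT voxels are filled by trilinear
#' lookup in fan coordinates.
#'
#' @param ct a \linkS4class{CTVolume}.
#' @param structures a \linkS4class{StructureSet} with at least BODY.
#' @param beam a \linkS4class{BeamSpec}.
#' @param thickness bolus thickness map (mm) on the design plane, or NULL
#'   for no bolus.
#' @param plane the \linkS4class{SBTPlane} the thickness map lives on
#'   (required when \code{thickness} is given).
#' @param cetTable a \linkS4class{CETTable} (default
#'   \code{\link{defaultCETTable}()}).
#' @param fanSpacing ray spacing of the internal fan grid at the isocenter
#'   plane, mm.
#' @param fanMargin lateral extent of the fan beyond the field edge, mm.
#' @param step radial sampling step along each ray, mm (default 0.5).
#' @param scatterGain optional bolus-shape scatter gain: > 0 adds a
#'   multiplicative term proportional to the local thickness deficit
#'   relative to the Gaussian-blurred neighborhood, emulating the extra
#'   electron scatter toward the midline under locally thin bolus. Default
#'   0 (off).
#' @param scatterRange blur range of the scatter term, mm.
#' @return a \linkS4class{DoseGrid} on the CT grid, \% of prescription (the
#'   open-field maximum is the prescription level).
#' @export
computeDose <- function(ct, structures, beam, thickness = NULL, plane = NULL,
                        cetTable = defaultCETTable(), fanSpacing = 2.5,
                        fanMargin = 20, step = 0.5, scatterGain = 0,
                        scatterRange = 10) {
  body <- structureMask(structures, "BODY")
  ax <- beamAxes(beam)
  model <- pddModel(beam@energy)
  halfField <- beam@applicator * 10 / 2

  fan <- buildSbtPlane(beam, margin = fanMargin, spacing = fanSpacing)
  nu <- length(fan@u); nv <- length(fan@v)
  rays <- planeRays(beam, fan)
  nr <- nrow(rays$dirs)

  # water-equivalent bolus path per fan ray (constant along the ray)
  bolusWED <- numeric(nr)
  if (!is.null(thickness)) {
    if (is.null(plane)) stop("plane required with a thickness map", call. = FALSE)
    U <- rep(fan@u, times = nv); V <- rep(fan@v, each = nu)
    bolusWED <- cetTable@bolusCET *
      pmax(bilinearSample(thickness, plane@u, plane@v, U, V, fill = 0), 0)
  }

  # radial sampling range: cover the CT bounding box for all rays
  lo <- ct@origin; hi <- ct@origin + dim(ct@voxels) * ct@spacing
  corners <- as.matrix(expand.grid(c(lo[1], hi[1]), c(lo[2], hi[2]),
                                   c(lo[3], hi[3])))
  sc <- corners - matrix(rays$source, 8, 3, byrow = TRUE)
  sRange <- range(sqrt(rowSums(sc^2)))
  s0 <- max(sRange[1] - 5, 1)
  s1 <- sRange[2] + 5
  sSteps <- seq(s0, s1, by = step)
  ns <- length(sSteps)

  huArr <- ct@voxels
  bodyNum <- array(as.numeric(body), dim = dim(body))
  wed <- matrix(0, nr, ns)
  acc <- bolusWED
  src <- rays$source
  for (k in seq_len(ns)) {
    mid <- sSteps[k] - step / 2
    P <- cbind(src[1] + mid * rays$dirs[, 1],
               src[2] + mid * rays$dirs[, 2],
               src[3] + mid * rays$dirs[, 3])
    inB <- trilinearSample(bodyNum, ct@origin, ct@spacing, P, fill = 0) >= 0.5
    if (any(inB)) {
      huMid <- trilinearSample(huArr, ct@origin, ct@spacing, P, fill = -1000)
      acc <- acc + ifelse(inB, cetAt(cetTable, huMid), 0) * step
    }
    wed[, k] <- acc
  }

  U <- rep(fan@u, times = nv); V <- rep(fan@v, each = nu)
  doseFan <- pddEval(model, as.vector(wed)) *
    lateralFactor(rep(U, times = ns), rep(V, times = ns),
                  as.vector(wed), halfField)
  doseFan <- array(doseFan, dim = c(nr, ns))

  if (scatterGain > 0 && !is.null(thickness)) {
    tFan <- matrix(bilinearSample(thickness, plane@u, plane@v, U, V, fill = 0),
                   nu, nv)
    blur <- gaussianBlur2D(tFan, scatterRange / fan@spacing)
    fac <- 1 + scatterGain * pmax(blur - tFan, 0) / 10
    doseFan <- doseFan * as.vector(fac)
  }

  # renormalize: open-field central-axis maximum = 100
  norm <- 100 * lateralFactor(0, 0, model$zmax, halfField)
  doseFan <- doseFan * (100 / norm)

  # resample onto CT voxels via fan coordinates (u, v at iso plane; radial s)
  d <- dim(ct@voxels)
  centers <- voxelCenters(d, ct@spacing, ct@origin)
  Wc <- centers - matrix(src, nrow(centers), 3, byrow = TRUE)
  tAxis <- Wc %*% ax$axis
  sVox <- sqrt(rowSums(Wc^2))
  uVox <- (Wc %*% ax$eu) * beam@sad / tAxis
  vVox <- (Wc %*% ax$ev) * beam@sad / tAxis
  ok <- tAxis > 0
  vals <- numeric(nrow(centers))
  fanArr <- array(doseFan, dim = c(nu, nv, ns))
  pts <- cbind(uVox[ok], vVox[ok], sVox[ok])
  # treat (u, v, s) as a regular grid for trilinear lookup
  # fan cell k holds the state at the step midpoint sSteps[k] - step/2
  vals[ok] <- trilinearSample(fanArr,
                              origin = c(fan@u[1] - fan@spacing / 2,
                                         fan@v[1] - fan@spacing / 2,
                                         sSteps[1] - step),
                              spacing = c(fan@spacing, fan@spacing, step),
                              pts = pts, fill = 0)
  doseGrid(array(pmax(vals, 0), dim = d), spacing = ct@spacing,
           origin = ct@origin)
}

# Separable Gaussian blur of a matrix (sigma in cells), reflecting edges.
gaussianBlur2D <- function(m, sigmaCells) {
  if (sigmaCells <= 0) return(m)
  r <- max(1L, ceiling(3 * sigmaCells))
  k <- exp(-(-r:r)^2 / (2 * sigmaCells^2)); k <- k / sum(k)
  pad <- function(x, n) x[c(pmin(pmax(seq(1 - n, length(x) + n), 1), length(x)))]
  blur1 <- function(vec) {
    v <- pad(vec, r)
    stats::filter(v, k, sides = 2)[(r + 1):(r + length(vec))]
  }
  m1 <- apply(m, 2, blur1)
  t(apply(m1, 1, blur1))
}
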