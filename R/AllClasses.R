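#' @import methods
NULL

#' CTVolume: a voxelized CT image in patient coordinates
#'
#' Stores the Hounsfield-unit voxel grid with its geometry. Arrays are indexed
#' \code{[i, j, k]} along patient axes (x, y, z) in mm; the center of voxel
#' (i, j, k) (1-based) is at \code{origin + (c(i, j, k) - 0.5) * spacing}.
#'
#' @slot voxels 3D integer-valued array of HU.
#' @slot spacing voxel spacing in mm per axis (length 3, all > 0).
#' @slot origin patient-coordinate position (mm) of the volume corner.
#' @slot orientation 3x3 direction-cosine matrix (axis-aligned identity
#'   supported).
#' @export
setClass("CTVolume", representation(
  voxels = "array", spacing = "numeric", origin = "numeric",
  orientation = "matrix"))

setValidity("CTVolume", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3) msg <- c(msg, "voxels must be a 3D array")
  if (length(object@spacing) != 3 || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be length 3 and > 0 on all axes")
  if (length(object@origin) != 3) msg <- c(msg, "origin must be length 3")
  rng <- range(object@voxels)
  if (rng[1] < -1024 || rng[2] > 4000)
    msg <- c(msg, "HU values must lie in [-1024, 4000]")
  if (!all(dim(object@orientation) == c(3, 3)))
    msg <- c(msg, "orientation must be a 3x3 matrix")
  if (length(msg)) msg else TRUE
})

#' Construct a CTVolume
#'
#' @param voxels 3D array of HU values.
#' @param spacing mm per axis.
#' @param origin mm, patient coordinates of the grid corner.
#' @param orientation direction cosines; default identity (axial, axis-aligned).
#' @return a \linkS4class{CTVolume}.
#' @export
ctVolume <- function(voxels, spacing, origin = c(0, 0, 0),
                     orientation = diag(3)) {
  new("CTVolume", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin), orientation = orientation)
}

#' StructureSet: named binary masks on a CT grid
#'
#' @slot masks named list of logical arrays, all the same shape as the CT.
#' @slot refDim the CT grid dimensions the masks live on.
#' @export
setClass("StructureSet", representation(masks = "list", refDim = "integer"))

setValidity("StructureSet", function(object) {
  msg <- character()
  if (length(object@masks) && is.null(names(object@masks)))
    msg <- c(msg, "masks must be named")
  for (nm in names(object@masks)) {
    m <- object@masks[[nm]]
    if (!is.logical(m)) msg <- c(msg, paste0("mask '", nm, "' must be logical"))
    if (!identical(dim(m), as.integer(object@refDim)))
      msg <- c(msg, paste0("mask '", nm, "' shape differs from the CT grid"))
  }
  if (all(c("PTV", "BODY") %in% names(object@masks))) {
    if (any(object@masks$PTV & !object@masks$BODY))
      msg <- c(msg, "PTV must be contained in BODY")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a StructureSet
#' @param masks named list of logical arrays (e.g. PTV, BODY, OARs).
#' @param ct the \linkS4class{CTVolume} the masks are defined on.
#' @return a \linkS4class{StructureSet}.
#' @export
structureSet <- function(masks, ct) {
  new("StructureSet", masks = masks, refDim = dim(ct@voxels))
}

#' DoseGrid: 3D dose in percent of prescription
#'
#' @slot dose 3D array, \% of prescription (100 = prescription).
#' @slot spacing,origin grid geometry in mm (normally the CT grid).
#' @export
setClass("DoseGrid", representation(
  dose = "array", spacing = "numeric", origin = "numeric"))

setValidity("DoseGrid", function(object) {
  msg <- character()
  if (length(dim(object@dose)) != 3) msg <- c(msg, "dose must be a 3D array")
  if (any(object@dose < 0)) msg <- c(msg, "dose must be non-negative")
  if (any(object@spacing <= 0)) msg <- c(msg, "spacing must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a DoseGrid
#' @param dose 3D array in \% of prescription.
#' @param spacing,origin grid geometry (mm).
#' @return a \linkS4class{DoseGrid}.
#' @export
doseGrid <- function(dose, spacing, origin = c(0, 0, 0)) {
  new("DoseGrid", dose = dose, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' PDDCurve: central-axis percentage depth dose samples
#'
#' @slot depth strictly increasing depths (mm).
#' @slot dose relative dose (\% of the curve maximum, max 100).
#' @export
setClass("PDDCurve", representation(depth = "numeric", dose = "numeric"))

setValidity("PDDCurve", function(object) {
  msg <- character()
  if (length(object@depth) < 10) msg <- c(msg, "need at least 10 samples")
  if (length(object@depth) != length(object@dose))
    msg <- c(msg, "depth and dose lengths differ")
  if (any(diff(object@depth) <= 0))
    msg <- c(msg, "depths must be strictly increasing")
  if (abs(max(object@dose) - 100) > 0.1)
    msg <- c(msg, "maximum dose must equal 100 within 0.1")
  if (length(msg)) msg else TRUE
})

#' Construct a PDDCurve
#' @param depth depths in mm (strictly increasing).
#' @param dose relative dose in \% of maximum.
#' @return a \linkS4class{PDDCurve}.
#' @export
pddCurve <- function(depth, dose) new("PDDCurve", depth = depth, dose = dose)

#' BeamSpec: electron beam description
#'
#' @slot energy nominal energy, MeV.
#' @slot applicator square applicator side length, cm.
#' @slot ssd source-to-surface distance, cm.
#' @slot gantry gantry angle, degrees (rotation in the x-z plane).
#' @slot isocenter mm, patient coordinates.
#' @slot sad source-axis distance of the virtual point source, mm.
#' @export
setClass("BeamSpec", representation(
  energy = "numeric", applicator = "numeric", ssd = "numeric",
  gantry = "numeric", isocenter = "numeric", sad = "numeric"))

setValidity("BeamSpec", function(object) {
  msg <- character()
  if (object@applicator <= 0) msg <- c(msg, "applicator must be > 0")
  if (object@ssd <= 0) msg <- c(msg, "SSD must be > 0")
  if (object@energy <= 0) msg <- c(msg, "energy must be > 0")
  if (length(object@isocenter) != 3) msg <- c(msg, "isocenter must be length 3")
  if (length(msg)) msg else TRUE
})

#' Construct a BeamSpec
#'
#' Standard clinical electron energies are 6, 9, 12 and 16 MeV; other values
#' are accepted (the depth-dose surrogate is parameterized continuously).
#'
#' @param energy MeV.
#' @param applicator square field side length, cm.
#' @param ssd source-to-surface distance, cm.
#' @param gantry gantry angle in degrees; 0 means the beam travels along +z.
#' @param isocenter mm patient coordinates.
#' @param sad virtual-source to isocenter distance in mm (default 1000).
#' @return a \linkS4class{BeamSpec}.
#' @export
beamSpec <- function(energy, applicator, ssd = 100, gantry = 0,
                     isocenter = c(0, 0, 0), sad = 1000) {
  new("BeamSpec", energy = energy, applicator = applicator, ssd = ssd,
      gantry = gantry, isocenter = as.numeric(isocenter), sad = sad)
}

#' SBTPlane: the 2D design grid for bolus thickness
#'
#' The plane contains the isocenter and is perpendicular to the beam central
#' axis. Grid point (i, j) sits at \code{center + u[i] * eu + v[j] * ev};
#' index origin (u = v = 0) is the central-axis intersection.
#'
#' @slot center isocenter, mm.
#' @slot eu,ev in-plane unit axes (eu = gantry-rotated lateral, ev = y).
#' @slot normal plane normal (parallel to the beam axis).
#' @slot spacing grid spacing, mm.
#' @slot u,v in-plane coordinates of the grid lines, mm (symmetric about 0).
#' @export
setClass("SBTPlane", representation(
  center = "numeric", eu = "numeric", ev = "numeric", normal = "numeric",
  spacing = "numeric", u = "numeric", v = "numeric"))

setValidity("SBTPlane", function(object) {
  msg <- character()
  if (object@spacing <= 0) msg <- c(msg, "spacing must be > 0")
  if (abs(sum(object@normal * object@eu)) > 1e-9 ||
      abs(sum(object@normal * object@ev)) > 1e-9)
    msg <- c(msg, "normal must be orthogonal to the in-plane axes")
  if (length(msg)) msg else TRUE
})

#' Ray: a divergent ray line from the virtual source
#'
#' @slot origin virtual source position, mm.
#' @slot direction unit direction.
#' @slot planePoint the design-grid point the ray passes through, mm.
#' @export
setClass("Ray", representation(
  origin = "numeric", direction = "numeric", planePoint = "numeric"))

setValidity("Ray", function(object) {
  if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-9)
    "direction must be normalized" else TRUE
})

#' SBTGrid: signed shift-of-bolus-thickness map on the design plane
#'
#' Positive values thicken the bolus along the corresponding ray, negative
#' values thin it. \code{valid} marks rays that intersect the PTV.
#'
#' @slot values matrix (mm of bolus material), dim = (length(u), length(v)).
#' @slot valid logical matrix, same shape.
#' @slot plane the \linkS4class{SBTPlane} the grid lives on.
#' @export
setClass("SBTGrid", representation(
  values = "matrix", valid = "matrix", plane = "SBTPlane"))

setValidity("SBTGrid", function(object) {
  msg <- character()
  if (!all(is.finite(object@values[object@valid])))
    msg <- c(msg, "SBT values on valid rays must be finite")
  if (!identical(dim(object@values), dim(object@valid)))
    msg <- c(msg, "values and valid must have the same shape")
  if (length(msg)) msg else TRUE
})

#' CETTable: HU to relative-density (CET) lookup
#'
#' Piecewise-linear mapping from Hounsfield units to density relative to
#' water, as obtained from a CT calibration curve. Also carries the bolus
#' material's CET scalar.
#'
#' @slot hu breakpoints, HU, strictly increasing.
#' @slot density relative density at the breakpoints, monotone non-decreasing.
#' @slot bolusCET CET of the bolus material (PLA default 1.119).
#' @export
setClass("CETTable", representation(
  hu = "numeric", density = "numeric", bolusCET = "numeric"))

setValidity("CETTable", function(object) {
  msg <- character()
  if (any(diff(object@hu) <= 0)) msg <- c(msg, "HU breakpoints must increase")
  if (any(diff(object@density) < 0))
    msg <- c(msg, "density must be monotone non-decreasing in HU")
  cet0 <- stats::approx(object@hu, object@density, xout = 0, rule = 2)$y
  if (abs(cet0 - 1) > 1e-6) msg <- c(msg, "CET(0 HU) must equal 1.000")
  if (object@bolusCET <= 0) msg <- c(msg, "bolusCET must be > 0")
  if (length(msg)) msg else TRUE
})

#' MarginKernel: Gaussian kernel for the PTV-margin adjustment
#'
#' \code{kerfMA(x) = exp(-x^2 / (2 sigma^2))}; \code{K1 = sigma *
#' sqrt(-2 ln 0.01)} is the radial distance over which the kernel rises from
#' 0.01 to 1, so \code{kerfMA(K1) = 0.01} exactly.
#'
#' @slot sigma kernel width, mm.
#' @slot k1 mm.
#' @slot borderWidth width of the border region inside the PTV projection, mm.
#' @export
setClass("MarginKernel", representation(
  sigma = "numeric", k1 = "numeric", borderWidth = "numeric"))

setValidity("MarginKernel", function(object) {
  msg <- character()
  if (object@sigma <= 0) msg <- c(msg, "sigma must be > 0")
  if (abs(object@k1 - object@sigma * sqrt(-2 * log(0.01))) > 1e-9)
    msg <- c(msg, "k1 must equal sigma * sqrt(-2 ln 0.01)")
  if (length(msg)) msg else TRUE
})

#' Construct a MarginKernel
#'
#' @param sigma kernel width in mm. The package default ties sigma to the
#'   beam as \code{sqrt(energy_MeV * applicator_cm)} mm (see
#'   \code{\link{defaultSigma}}).
#' @param borderWidth border width inside the PTV projection, mm (default 10).
#' @return a \linkS4class{MarginKernel}.
#' @export
marginKernel <- function(sigma, borderWidth = 10) {
  new("MarginKernel", sigma = sigma, k1 = sigma * sqrt(-2 * log(0.01)),
      borderWidth = borderWidth)
}

#' BolusSolid: watertight triangulated bolus between skin and outer surface
#'
#' Built on the design grid: inner vertices on the patient surface along each
#' ray, outer vertices displaced toward the source by the local thickness, a
#' side skirt closing the boundary. The per-grid-point source distances of
#' both surfaces are retained so the solid can be voxelized exactly.
#'
#' @slot vertices n x 3 matrix, mm, patient frame.
#' @slot triangles m x 3 integer matrix of vertex indices (CCW outward).
#' @slot plane the design plane the solid was built on.
#' @slot beam the beam used for the ray construction.
#' @slot sInner,sOuter matrices of distances from the virtual source to the
#'   inner/outer surface per grid point (mm).
#' @slot thickness the thickness map the solid realizes (mm).
#' @export
setClass("BolusSolid", representation(
  vertices = "matrix", triangles = "matrix", plane = "SBTPlane",
  beam = "BeamSpec", sInner = "matrix", sOuter = "matrix",
  thickness = "matrix"))

setValidity("BolusSolid", function(object) {
  msg <- character()
  if (ncol(object@vertices) != 3) msg <- c(msg, "vertices must be n x 3")
  if (ncol(object@triangles) != 3) msg <- c(msg, "triangles must be m x 3")
  if (nrow(object@triangles) &&
      (max(object@triangles) > nrow(object@vertices) || min(object@triangles) < 1))
    msg <- c(msg, "triangle indices out of range")
  if (length(msg)) msg else TRUE
})

#' PlanMetrics: dosimetric summary of one iteration
#'
#' @slot v90 \% of PTV volume receiving at least 90\% of prescription.
#' @slot dmax maximum dose in BODY, \% of prescription.
#' @slot conformity PTV volume / volume enclosed by the 90\% isodose.
#' @slot oar named list of per-OAR mean and max dose (\%).
#' @slot iteration iteration index (0 = initial, no-bolus plan).
#' @export
setClass("PlanMetrics", representation(
  v90 = "numeric", dmax = "numeric", conformity = "numeric",
  oar = "list", iteration = "integer"))

setValidity("PlanMetrics", function(object) {
  msg <- character()
  if (object@v90 < 0 || object@v90 > 100) msg <- c(msg, "v90 must be in [0, 100]")
  if (length(msg)) msg else TRUE
})
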