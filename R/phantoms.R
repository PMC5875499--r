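# Synthetic phantom generators. These replicate the desk-scale test
# geometries: a 20 x 20 x 20 cm water cube with a wedge-shaped PTV and
# optional bone/air slabs distal to the target, and curved-surface phantoms
# (sinusoidal or spherical-cap entrance surface) with an embedded PTV.
# All generators are deterministic given their arguments; optional HU noise
# is seeded.

materialHU <- c(water = 0, bone = 800, air = -1000, pla = 160)

applyHUNoise <- function(hu, body, noiseSD, seed) {
  if (noiseSD <= 0) return(hu)
  set.seed(seed)
  n <- sum(body)
  hu[body] <- as.integer(round(hu[body] + stats::rnorm(n, 0, noiseSD)))
  pmin(pmax(hu, -1024L), 4000L)
}

#' Wedge-PTV water-cube phantom
#'
#' A water cube (default 20 x 20 x 20 cm, 8000 cm^3) with an air gap above
#' the entrance surface, a wedge-shaped PTV whose distal surface is a planar
#' ramp, and optional inhomogeneity slabs distal to the PTV. The default
#' inserts are a bone slab and an air slab side by side under the target.
#'
#' Coordinates: the entrance surface is z = 0, centered on x = y = 0; the
#' beam travels along +z from above.
#'
#' @param side cube side length, mm.
#' @param spacing isotropic voxel spacing, mm (2.5 default; use 1 for
#'   fine-grid unit tests).
#' @param airAbove air padding above the entrance surface, mm.
#' @param ptvLateral lateral side length of the (square-section) PTV, mm.
#' @param ptvProximal depth of the proximal PTV surface, mm.
#' @param ptvDistalMin,ptvDistalMax distal-surface ramp depths at the two
#'   lateral ends (equal values give a flat distal surface), mm.
#' @param inserts list of inserts, each \code{list(material =
#'   "bone"|"air"|"water"|"pla", x = c(lo, hi), y = c(lo, hi), z = c(lo,
#'   hi))} in mm. \code{NULL} disables; the default places a bone and an air
#'   slab distal to the PTV.
#' @param noiseSD optional Gaussian HU noise sigma (default 0 = off).
#' @param seed RNG seed for the noise.
#' @return list with elements \code{ct} (\linkS4class{CTVolume}) and
#'   \code{structures} (\linkS4class{StructureSet} with BODY, PTV and one
#'   mask per insert).
#' @export
wedgePhantom <- function(side = 200, spacing = 2.5, airAbove = 20,
                         ptvLateral = 80, ptvProximal = 5,
                         ptvDistalMin = 15, ptvDistalMax = 35,
                         inserts = list(
                           list(material = "bone", x = c(-40, -5),
                                y = c(-40, 40), z = c(40, 55)),
                           list(material = "air", x = c(5, 40),
                                y = c(-40, 40), z = c(40, 55))),
                         noiseSD = 0, seed = 1) {
  d <- c(round(side / spacing), round(side / spacing),
         round((side + airAbove) / spacing))
  origin <- c(-side / 2, -side / 2, -airAbove)
  xs <- origin[1] + (seq_len(d[1]) - 0.5) * spacing
  ys <- origin[2] + (seq_len(d[2]) - 0.5) * spacing
  zs <- origin[3] + (seq_len(d[3]) - 0.5) * spacing
  X <- array(rep(xs, times = d[2] * d[3]), dim = d)
  Y <- array(rep(rep(ys, each = d[1]), times = d[3]), dim = d)
  Z <- array(rep(zs, each = d[1] * d[2]), dim = d)

  body <- Z >= 0 & Z <= side
  hu <- array(-1000L, dim = d)
  hu[body] <- 0L

  half <- ptvLateral / 2
  distal <- ptvDistalMin +
    (X + half) / ptvLateral * (ptvDistalMax - ptvDistalMin)
  ptv <- abs(X) <= half & abs(Y) <= half & Z >= ptvProximal & Z <= distal
  ptv <- ptv & body

  masks <- list(BODY = body, PTV = ptv)
  for (ins in inserts %||% list()) {
    if (!ins$material %in% names(materialHU))
      stop("unknown insert material '", ins$material, "'", call. = FALSE)
    box <- X >= ins$x[1] & X <= ins$x[2] & Y >= ins$y[1] & Y <= ins$y[2] &
           Z >= ins$z[1] & Z <= ins$z[2]
    if (!all(box & body | !box))
      stop("insert extends outside the phantom body", call. = FALSE)
    if (any(box & ptv)) stop("insert overlaps the PTV", call. = FALSE)
    hu[box] <- as.integer(materialHU[[ins$material]])
    masks[[toupper(ins$material)]] <- box
  }
  hu <- applyHUNoise(hu, body, noiseSD, seed)

  ct <- ctVolume(hu, spacing = rep(spacing, 3), origin = origin)
  list(ct = ct, structures = structureSet(masks, ct))
}

#' Curved-surface phantom with embedded PTV
#'
#' A slab phantom whose entrance surface is modulated: sinusoidal ridges
#' (foot-like) or a spherical cap (head-like). The PTV follows the surface
#' at a configurable depth.
#'
#' @param profile \code{"sinusoidal"} or \code{"spherical"}.
#' @param side lateral size and water depth below z = 0, mm.
#' @param spacing voxel spacing, mm.
#' @param airAbove air padding above the highest surface point, mm.
#' @param amplitude peak-to-trough surface height for the sinusoid, mm
#'   (0 gives a flat slab).
#' @param period sinusoid period along x, mm.
#' @param capRadius sphere radius for the spherical cap, mm.
#' @param ptvMargin depth of the proximal PTV surface below the local
#'   entrance surface, mm (must be > 0 so the PTV does not break through).
#' @param ptvThickness PTV thickness along z, mm.
#' @param ptvLateral lateral side length of the PTV, mm.
#' @param noiseSD,seed optional seeded Gaussian HU noise.
#' @return list with \code{ct}, \code{structures} and the analytic surface
#'   height field \code{surface} (matrix over the in-plane grid, mm).
#' @export
curvedPhantom <- function(profile = c("sinusoidal", "spherical"),
                          side = 120, spacing = 2, airAbove = NULL,
                          amplitude = 20, period = 60, capRadius = 100,
                          ptvMargin = 5, ptvThickness = 15, ptvLateral = 60,
                          noiseSD = 0, seed = 1) {
  profile <- match.arg(profile)
  if (ptvMargin <= 0) stop("PTV would break through the surface", call. = FALSE)
  xs1 <- seq(-side / 2 + spacing / 2, side / 2 - spacing / 2, by = spacing)
  surf <- function(x, y) {
    if (profile == "sinusoidal") {
      if (amplitude == 0) rep(0, length(x))
      else amplitude / 2 * (1 - cos(2 * pi * x / period))
    } else {
      r2 <- x^2 + y^2
      capRadius - sqrt(pmax(capRadius^2 - r2, 0))
    }
  }
  zmaxSurf <- max(surf(xs1, 0), surf(0, xs1),
                  surf(rep(xs1, length(xs1)), rep(xs1, each = length(xs1))))
  airAbove <- airAbove %||% (ceiling(zmaxSurf / spacing) * spacing + 10)

  d <- c(length(xs1), length(xs1),
         round((side + airAbove) / spacing))
  origin <- c(-side / 2, -side / 2, -airAbove)
  zs <- origin[3] + (seq_len(d[3]) - 0.5) * spacing
  X <- array(rep(xs1, times = d[2] * d[3]), dim = d)
  Y <- array(rep(rep(xs1, each = d[1]), times = d[3]), dim = d)
  Z <- array(rep(zs, each = d[1] * d[2]), dim = d)

  S <- array(surf(as.vector(X), as.vector(Y)), dim = d)
  body <- Z >= S & Z <= side
  hu <- array(-1000L, dim = d)
  hu[body] <- 0L

  half <- ptvLateral / 2
  ptv <- abs(X) <= half & abs(Y) <= half &
         Z >= S + ptvMargin & Z <= S + ptvMargin + ptvThickness & body
  hu <- applyHUNoise(hu, body, noiseSD, seed)

  ct <- ctVolume(hu, spacing = rep(spacing, 3), origin = origin)
  heights <- matrix(surf(rep(xs1, length(xs1)), rep(xs1, each = length(xs1))),
                    d[1], d[2])
  list(ct = ct,
       structures = structureSet(list(BODY = body, PTV = ptv), ct),
       surface = heights)
}

#' Synthetic PDD curve through a slab stack
#'
#' Generates a central-axis depth-dose curve from the broad-beam surrogate,
#' evaluated at the water-equivalent depth through an ordered stack of slabs
#' replacing the superficial material (as in a slab-calibration measurement).
#' An empty stack yields the open-water curve.
#'
#' @param energy beam energy, MeV (6, 9, 12 or 16 are the standard set).
#' @param stack list of slabs, each \code{list(thickness = mm, cet = )},
#'   ordered from the surface down; \code{NULL} or \code{list()} for open
#'   water.
#' @param zmax maximum geometric depth sampled, mm (default 1.4 x practical
#'   range).
#' @param step depth sampling step, mm.
#' @return a \linkS4class{PDDCurve} (renormalized so its maximum is 100).
#' @export
pddFixture <- function(energy, stack = list(), zmax = NULL, step = 0.5) {
  for (s in stack %||% list())
    if (s$thickness < 0) stop("negative slab thickness", call. = FALSE)
  model <- pddModel(energy)
  zmax <- zmax %||% (1.4 * model$Rp)
  z <- seq(0, zmax, by = step)
  zeff <- effectiveDepth(z, stack)
  dose <- pddEval(model, zeff)
  pddCurve(depth = z, dose = dose / max(dose) * 100)
}

# Water-equivalent depth of geometric depth z through an ordered slab stack
# replacing the superficial material (water beyond the stack).
effectiveDepth <- function(z, stack) {
  zeff <- numeric(length(z))
  cum <- 0
  for (s in stack %||% list()) {
    zeff <- zeff + s$cet * pmin(pmax(z - cum, 0), s$thickness)
    cum <- cum + s$thickness
  }
  zeff + pmax(z - cum, 0)
}

#' Build a phantom from a YAML spec
#'
#' Dispatches on \code{type: wedge | curved}; remaining fields are passed to
#' \code{\link{wedgePhantom}} or \code{\link{curvedPhantom}} (insert boxes as
#' nested lists).
#'
#' @param path YAML file, or an equivalent named list.
#' @return the generator's result list.
#' @export
phantomFromSpec <- function(path) {
  y <- if (is.character(path)) yaml::read_yaml(path) else path
  type <- y$type %||% "wedge"
  y$type <- NULL
  if (!is.null(y$inserts))
    y$inserts <- lapply(y$inserts, function(i) {
      i$x <- as.numeric(i$x); i$y <- as.numeric(i$y); i$z <- as.numeric(i$z); i
    })
  switch(type,
         wedge = do.call(wedgePhantom, y),
         curved = do.call(curvedPhantom, y),
         stop("unknown phantom type '", type, "'", call. = FALSE))
}
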