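# The design iteration loop: compute dose -> extract along-ray surfaces ->
# SBT -> five regional operators -> update thickness -> repeat until the
# coverage target and hot-spot cap are met or the iteration budget runs
# out. The dose stage is pluggable: the built-in broad-beam surrogate, or
# any function (e.g. wrapping an externally computed dose grid per
# iteration).

#' Design configuration
#'
#' @param beam a \linkS4class{BeamSpec}.
#' @param planeSpacing design-grid spacing, mm (default 2.5).
#' @param planeMargin design-grid margin beyond the field edge, mm.
#' @param SF smoothing factor, mm: 5 / 10 / 20 for low / medium / high
#'   (default 10).
#' @param sigma margin-kernel width, mm; default
#'   \code{\link{defaultSigma}(beam)}.
#' @param borderWidth PTV-margin border width, mm (default 10).
#' @param cetTable a \linkS4class{CETTable}.
#' @param engine \code{"surrogate"} or a function
#'   \code{(ct, structures, beam, thickness, plane, iteration) -> DoseGrid}.
#' @param level covering isodose level, \% (default 90).
#' @param hotspotThreshold hot-spot criterion, \% (default 110).
#' @param v90Target stopping coverage target, \% (default 98).
#' @param dmaxCap stopping maximum-dose cap, \% (default 110).
#' @param gapTol conformity tolerance: RMS over PTV rays of the
#'   water-equivalent gap between the distal covering isodose and the
#'   distal PTV surface, mm (default 2; NULL disables). Coverage alone does
#'   not measure conformity of the covering isodose to the distal target
#'   surface, which is the objective of the design, so acceptability
#'   requires all three. The gap is measured in water-equivalent (CET-
#'   weighted) millimeters because the geometric crossing depth is
#'   ill-conditioned where the dose gradient collapses (e.g. beyond the
#'   target inside an air cavity), and over the interior of the PTV
#'   projection only (excluding the margin border), because the
#'   margin-adjustment operator deliberately deviates from conformity
#'   inside the border to compensate edge-scatter underdosing.
#' @param maxIterations iteration budget (default 5; 0 returns only the
#'   initial no-bolus metrics).
#' @param thicknessCap printability cap on bolus thickness, mm (default 40;
#'   exceeding rays are clamped with a warning).
#' @param shellThickness thickness of the bolus shell that defines the
#'   available surface in the initial plan, mm (geometry metadata only; the
#'   initial dose is computed without bolus).
#' @param scatterGain optional bolus-shape scatter gain of the surrogate.
#' @param seed RNG seed recorded with the run (the pipeline itself is
#'   deterministic).
#' @return a config list for \code{\link{runDesign}}.
#' @export
designConfig <- function(beam, planeSpacing = 2.5, planeMargin = 10,
                         SF = 10, sigma = NULL, borderWidth = 10,
                         cetTable = defaultCETTable(), engine = "surrogate",
                         level = 90, hotspotThreshold = 110,
                         v90Target = 98, dmaxCap = 110, gapTol = 2,
                         maxIterations = 5,
                         thicknessCap = 40, shellThickness = 10,
                         scatterGain = 0, seed = 1) {
  stopifnot(level > 0, level <= 200, v90Target > 0, v90Target <= 100,
            dmaxCap > 0, dmaxCap <= 200)
  list(beam = beam, planeSpacing = planeSpacing, planeMargin = planeMargin,
       SF = SF, sigma = sigma %||% defaultSigma(beam),
       borderWidth = borderWidth, cetTable = cetTable, engine = engine,
       level = level, hotspotThreshold = hotspotThreshold,
       v90Target = v90Target, dmaxCap = dmaxCap, gapTol = gapTol,
       maxIterations = maxIterations, thicknessCap = thicknessCap,
       shellThickness = shellThickness, scatterGain = scatterGain,
       seed = seed)
}

#' Plan metrics by voxel counting
#'
#' @param dose a \linkS4class{DoseGrid} on the CT grid.
#' @param structures a \linkS4class{StructureSet} with PTV and BODY; any
#'   other structure is summarized as an OAR.
#' @param level coverage level, \% (default 90).
#' @param iteration iteration index stored in the result.
#' @return a \linkS4class{PlanMetrics}.
#' @export
evaluatePlan <- function(dose, structures, level = 90, iteration = 0L) {
  ptv <- structureMask(structures, "PTV")
  body <- structureMask(structures, "BODY")
  if (!any(ptv)) stop("empty PTV", call. = FALSE)
  dv <- dose@dose
  v90 <- 100 * mean(dv[ptv] >= level)
  dmax <- max(dv[body])
  enclosed <- sum(dv >= level & body)
  conf <- if (enclosed > 0) sum(ptv) / enclosed else Inf
  oar <- list()
  for (nm in setdiff(structureNames(structures), c("PTV", "BODY"))) {
    m <- structureMask(structures, nm)
    if (any(m))
      oar[[nm]] <- c(mean = mean(dv[m]), max = max(dv[m]))
  }
  new("PlanMetrics", v90 = v90, dmax = dmax, conformity = conf, oar = oar,
      iteration = as.integer(iteration))
}

# Per-ray distal PTV depths and distal isodose depths over the design grid.
rayDepths <- function(plane, rays, structures, ct, dose, level) {
  nu <- length(plane@u); nv <- length(plane@v)
  ptv <- structureMask(structures, "PTV")
  ptvD <- matrix(NA_real_, nu, nv)
  isoD <- matrix(NA_real_, nu, nv)
  for (j in seq_len(nv)) for (i in seq_len(nu)) {
    r <- (j - 1) * nu + i
    iv <- rayMaskInterval(rays$source, rays$dirs[r, ], ptv, ct)
    if (is.null(iv)) next
    ptvD[i, j] <- iv["distal"]
    iso <- isodoseDistalDepth(rays$source, rays$dirs[r, ], dose, level)
    if (!is.null(iso)) isoD[i, j] <- iso
  }
  list(ptv = ptvD, iso = isoD)
}

#' Run the iterative bolus design
#'
#' Implements the full workflow: an initial no-bolus dose calculation, then
#' per iteration (i) along-ray extraction of the distal PTV and distal
#' covering-isodose depths, (ii) the CET-scaled SBT estimate, (iii) the five
#' regional modulation operators in fixed order, (iv) the thickness update,
#' and (v) a fresh dose calculation. Stops when V90 >= target and Dmax <=
#' cap, when V90 fails to improve for two consecutive iterations, or at the
#' iteration budget.
#'
#' @param ct a \linkS4class{CTVolume}.
#' @param structures a \linkS4class{StructureSet} with PTV and BODY.
#' @param config from \code{\link{designConfig}}.
#' @param verbose print per-iteration progress.
#' @return list with \code{thickness} (matrix, mm), \code{plane},
#'   \code{solid} (\linkS4class{BolusSolid} or NULL), \code{metrics} (list
#'   of \linkS4class{PlanMetrics}, index 1 = initial plan), \code{dose}
#'   (final \linkS4class{DoseGrid}), \code{log} (per-iteration operator
#'   statistics) and \code{converged}.
#' @export
runDesign <- function(ct, structures, config, verbose = FALSE) {
  beam <- config$beam
  plane <- buildSbtPlane(beam, margin = config$planeMargin,
                         spacing = config$planeSpacing)
  rays <- planeRays(beam, plane)
  body <- structureMask(structures, "BODY")
  ptv <- structureMask(structures, "PTV")
  aperture <- apertureRegion(beam, plane, beyond = 10)
  kernel <- marginKernel(config$sigma, config$borderWidth)
  engine <- config$engine
  callEngine <- function(thk, it) {
    if (is.function(engine)) {
      engine(ct, structures, beam, thk, plane, it)
    } else {
      computeDose(ct, structures, beam, thickness = thk, plane = plane,
                  cetTable = config$cetTable,
                  fanSpacing = min(config$planeSpacing, 2.5),
                  scatterGain = config$scatterGain)
    }
  }
  thickness <- matrix(0, length(plane@u), length(plane@v))
  dose <- callEngine(NULL, 0L)
  metrics <- list(evaluatePlan(dose, structures, config$level, 0L))
  if (verbose) show(metrics[[1]])
  log <- list()
  converged <- FALSE
  # water-equivalent distal gap per ray = SBT * CET_bolus, over the
  # interior of the PTV projection (the margin border deliberately
  # deviates from conformity)
  gapRMS <- function(sbtGrid) {
    val <- validRays(sbtGrid)
    interior <- val & maskEdgeDistance(val, plane@spacing) > config$borderWidth
    if (!any(interior)) interior <- val
    g <- sbtValues(sbtGrid)[interior] * config$cetTable@bolusCET
    if (length(g)) sqrt(mean(g^2)) else Inf
  }
  if (config$maxIterations >= 1) {
    dep <- rayDepths(plane, rays, structures, ct, dose, config$level)
    sbtNext <- computeSBT(plane, rays, dep$ptv, dep$iso, ct, config$cetTable)
    for (it in seq_len(config$maxIterations)) {
      sbt <- sbtNext
      opStats <- list(flagged = attr(sbt, "flagged"))
      stage <- function(x, nm) {
        v <- sbtValues(x)
        opStats[[nm]] <<- c(min = min(v), max = max(v))
        x
      }
      sbt <- stage(sbt, "raw")
      hs <- hotspotRegion(dose, body, plane, beam, ct,
                          config$hotspotThreshold)
      sbt <- stage(hotspotSmoothing(sbt, hs, config$SF), "hotspot")
      uc <- undercoverageRegion(dose, ptv, plane, beam, config$level)
      sbt <- stage(coverageSmoothing(sbt, uc, config$SF), "coverage")
      sbt <- stage(irregularitySmoothing(sbt, config$SF), "irregularity")
      sbt <- stage(marginAdjustment(sbt, validRays(sbt), kernel), "margin")
      sbt <- stage(extrudeOutside(sbt, validRays(sbt), aperture), "extrude")
      thickness <- applySBT(thickness, sbt)
      opStats$clamped <- attr(thickness, "clamped")
      if (any(thickness > config$thicknessCap)) {
        warning("thickness cap ", config$thicknessCap, " mm reached")
        thickness <- pmin(thickness, config$thicknessCap)
      }
      dose <- callEngine(thickness, it)
      dep <- rayDepths(plane, rays, structures, ct, dose, config$level)
      sbtNext <- computeSBT(plane, rays, dep$ptv, dep$iso, ct,
                            config$cetTable)
      m <- evaluatePlan(dose, structures, config$level, it)
      metrics[[it + 1]] <- m
      opStats$gapRMS <- gapRMS(sbtNext)
      log[[it]] <- opStats
      if (verbose) {
        show(m)
        message(sprintf("  water-equivalent distal gap RMS: %.2f mm",
                        opStats$gapRMS))
      }
      if (m@v90 >= config$v90Target && m@dmax <= config$dmaxCap &&
          (is.null(config$gapTol) || opStats$gapRMS <= config$gapTol)) {
        converged <- TRUE
        break
      }
      if (it >= 2 && m@v90 < config$v90Target &&
          m@v90 <= metrics[[it]]@v90 + 1e-9 &&
          metrics[[it]]@v90 <= metrics[[it - 1]]@v90 + 1e-9) {
        warning("V90 not improving for two consecutive iterations; stopping")
        break
      }
    }
  }
  solid <- if (any(thickness > 0))
    buildSolid(thickness, body, plane, beam, ct) else NULL
  list(thickness = thickness, plane = plane, solid = solid,
       metrics = metrics, dose = dose, log = log, converged = converged)
}

#' Export a DVH table
#'
#' Cumulative dose-volume histogram per structure, as a data frame suitable
#' for CSV export.
#'
#' @param dose a \linkS4class{DoseGrid}.
#' @param structures a \linkS4class{StructureSet}.
#' @param step dose bin width, \%.
#' @return data frame with columns structure, dose_percent, volume_percent.
#' @export
dvhTable <- function(dose, structures, step = 1) {
  bins <- seq(0, ceiling(max(dose@dose)) + step, by = step)
  out <- list()
  for (nm in structureNames(structures)) {
    m <- structureMask(structures, nm)
    if (!any(m)) next
    dv <- dose@dose[m]
    vol <- vapply(bins, function(b) 100 * mean(dv >= b), numeric(1))
    out[[nm]] <- data.frame(structure = nm, dose_percent = bins,
                            volume_percent = vol)
  }
  do.call(rbind, out)
}
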