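# Generics, accessors and show methods for the core classes.

#' @rdname accessors
#' @param object,x an object of one of the package classes.
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))
#' @rdname accessors
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))
#' @rdname accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @rdname accessors
#' @export
setGeneric("doseArray", function(x) standardGeneric("doseArray"))
#' @rdname accessors
#' @export
setGeneric("structureNames", function(x) standardGeneric("structureNames"))
#' @rdname accessors
#' @param name structure name.
#' @export
setGeneric("structureMask", function(x, name) standardGeneric("structureMask"))
#' @rdname accessors
#' @export
setGeneric("sbtValues", function(x) standardGeneric("sbtValues"))
#' @rdname accessors
#' @export
setGeneric("validRays", function(x) standardGeneric("validRays"))

#' Accessors for package classes
#'
#' Slot access for \linkS4class{CTVolume}, \linkS4class{DoseGrid},
#' \linkS4class{StructureSet} and \linkS4class{SBTGrid}.
#'
#' @name accessors
#' @return the corresponding slot content.
NULL

#' @rdname accessors
#' @export
setMethod("voxels", "CTVolume", function(x) x@voxels)
#' @rdname accessors
#' @export
setMethod("gridSpacing", "CTVolume", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("gridOrigin", "CTVolume", function(x) x@origin)
#' @rdname accessors
#' @export
setMethod("gridSpacing", "DoseGrid", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("gridOrigin", "DoseGrid", function(x) x@origin)
#' @rdname accessors
#' @export
setMethod("doseArray", "DoseGrid", function(x) x@dose)
#' @rdname accessors
#' @export
setMethod("structureNames", "StructureSet", function(x) names(x@masks))
#' @rdname accessors
#' @export
setMethod("structureMask", "StructureSet", function(x, name) {
  if (!name %in% names(x@masks)) stop("no structure named '", name, "'")
  x@masks[[name]]
})
#' @rdname accessors
#' @export
setMethod("sbtValues", "SBTGrid", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("validRays", "SBTGrid", function(x) x@valid)

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@voxels)
  cat("CTVolume:", paste(d, collapse = " x "), "voxels,",
      paste(signif(object@spacing, 4), collapse = " x "), "mm spacing\n")
  cat("  origin (mm):", paste(signif(object@origin, 5), collapse = ", "), "\n")
  cat("  HU range:", paste(range(object@voxels), collapse = " .. "), "\n")
})

setMethod("show", "StructureSet", function(object) {
  cat("StructureSet on a", paste(object@refDim, collapse = " x "), "grid\n")
  for (nm in names(object@masks))
    cat(sprintf("  %-12s %d voxels\n", nm, sum(object@masks[[nm]])))
})

setMethod("show", "DoseGrid", function(object) {
  d <- dim(object@dose)
  cat("DoseGrid:", paste(d, collapse = " x "), "voxels, max",
      sprintf("%.1f%%", max(object@dose)), "of prescription\n")
})

setMethod("show", "PDDCurve", function(object) {
  cat(sprintf("PDDCurve: %d samples, depth %.1f..%.1f mm, R50 ~ %.1f mm\n",
              length(object@depth), min(object@depth), max(object@depth),
              {
                f <- which(object@dose < 50 &
                           object@depth > object@depth[which.max(object@dose)])
                if (length(f)) object@depth[f[1]] else NA_real_
              }))
})

setMethod("show", "BeamSpec", function(object) {
  cat(sprintf("BeamSpec: %g MeV, %g x %g cm applicator, SSD %g cm, gantry %g deg\n",
              object@energy, object@applicator, object@applicator,
              object@ssd, object@gantry))
})

setMethod("show", "SBTPlane", function(object) {
  cat(sprintf("SBTPlane: %d x %d points, %.2f mm spacing, extent %.0f x %.0f mm\n",
              length(object@u), length(object@v), object@spacing,
              diff(range(object@u)), diff(range(object@v))))
})

setMethod("show", "SBTGrid", function(object) {
  v <- object@values[object@valid]
  cat(sprintf("SBTGrid: %d x %d, %d valid rays", nrow(object@values),
              ncol(object@values), sum(object@valid)))
  if (length(v)) cat(sprintf(", range %.2f .. %.2f mm", min(v), max(v)))
  cat("\n")
})

setMethod("show", "BolusSolid", function(object) {
  cat(sprintf("BolusSolid: %d vertices, %d triangles, thickness %.1f..%.1f mm\n",
              nrow(object@vertices), nrow(object@triangles),
              min(object@thickness), max(object@thickness)))
})

setMethod("show", "PlanMetrics", function(object) {
  cat(sprintf("PlanMetrics (iteration %d): V90 = %.1f%%, Dmax = %.1f%%, CI = %.2f\n",
              object@iteration, object@v90, object@dmax, object@conformity))
  for (nm in names(object@oar))
    cat(sprintf("  %-12s mean %.1f%%, max %.1f%%\n", nm,
                object@oar[[nm]]["mean"], object@oar[[nm]]["max"]))
})
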