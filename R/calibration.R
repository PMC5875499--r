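# CET calibration from depth-dose curves. Replacing the superficial t mm of
# water with a slab of CET > 1 shifts the falloff of the PDD shallower by
#   z_eff - z_real = (CET - 1) * t,
# so the slab CET follows from the slope of measured shift vs slab
# thickness. The shift between two curves is located by chi-square matching
# of the falloff region.

#' Chi-square shift between two PDD curves
#'
#' Finds the shift s minimizing \code{sum((slab(z) - ref(z + s))^2)} over
#' the 20--80\% falloff window of the slab curve (curves linearly
#' interpolated), by grid search with parabolic refinement of the discrete
#' minimum. Positive s means the slab curve is shallower than the
#' reference.
#'
#' @param pddRef reference (open-water) \linkS4class{PDDCurve}.
#' @param pddSlab slab-measurement \linkS4class{PDDCurve}.
#' @param search half-width of the shift search interval, mm (default 10).
#' @param step grid-search step, mm (default 0.05).
#' @return the shift in mm.
#' @export
chi2Shift <- function(pddRef, pddSlab, search = 10, step = 0.05) {
  slabF <- stats::approxfun(pddSlab@depth, pddSlab@dose, rule = 2)
  refF <- stats::approxfun(pddRef@depth, pddRef@dose, rule = 2)
  # falloff window of the slab curve: 20..80% beyond its maximum
  zPeak <- pddSlab@depth[which.max(pddSlab@dose)]
  zGrid <- seq(zPeak, max(pddSlab@depth), by = 0.1)
  dv <- slabF(zGrid)
  win <- zGrid[dv >= 20 & dv <= 80]
  if (length(win) < 5)
    stop("falloff window too small for chi-square matching", call. = FALSE)
  shifts <- seq(-search, search, by = step)
  chi2 <- vapply(shifts, function(s) sum((slabF(win) - refF(win + s))^2),
                 numeric(1))
  k <- which.min(chi2)
  if (k == 1 || k == length(shifts))
    stop("chi-square minimum at the search boundary; widen the search range",
         call. = FALSE)
  # parabolic refinement through the three points around the minimum
  y1 <- chi2[k - 1]; y2 <- chi2[k]; y3 <- chi2[k + 1]
  denom <- y1 - 2 * y2 + y3
  offset <- if (abs(denom) > 1e-15) 0.5 * (y1 - y3) / denom else 0
  shifts[k] + offset * step
}

#' CET from measured shifts of multiple slabs
#'
#' Least-squares slope of shift vs thickness through the origin;
#' \code{CET = 1 + slope}. With a single slab the direct ratio is returned
#' without an uncertainty.
#'
#' @param shifts measured falloff shifts, mm.
#' @param thicknesses slab thicknesses, mm (> 0, same length).
#' @return list with \code{cet} and \code{uncertainty} (NA for one slab),
#'   estimated from the fit residuals.
#' @export
cetFromShifts <- function(shifts, thicknesses) {
  stopifnot(length(shifts) == length(thicknesses), all(thicknesses > 0))
  if (length(shifts) == 1)
    return(list(cet = 1 + shifts / thicknesses, uncertainty = NA_real_))
  slope <- sum(shifts * thicknesses) / sum(thicknesses^2)
  res <- shifts - slope * thicknesses
  se <- sqrt(sum(res^2) / (length(shifts) - 1) / sum(thicknesses^2))
  list(cet = 1 + slope, uncertainty = se)
}

#' CET from mass density
#'
#' CET is approximated by the material's density relative to water
#' (1.000 g/cm^3); PLA at 1.119 g/cm^3 gives CET 1.119.
#'
#' @param density mass density in g/cm^3 (> 0).
#' @return the CET value.
#' @export
cetFromDensity <- function(density) {
  stopifnot(density > 0)
  density / 1.000
}

#' Full slab-calibration report
#'
#' Runs \code{\link{chi2Shift}} for each slab curve against the reference
#' and pools the shifts into a CET estimate; optionally writes the report
#' as YAML.
#'
#' @param pddRef reference \linkS4class{PDDCurve}.
#' @param slabCurves list of slab \linkS4class{PDDCurve}s.
#' @param thicknesses slab thicknesses, mm.
#' @param out optional YAML output path.
#' @return list with per-slab \code{shifts}, pooled \code{cet} and
#'   \code{uncertainty}.
#' @export
calibrateCET <- function(pddRef, slabCurves, thicknesses, out = NULL) {
  shifts <- vapply(slabCurves, function(c_) chi2Shift(pddRef, c_), numeric(1))
  est <- cetFromShifts(shifts, thicknesses)
  rep_ <- list(shifts_mm = as.numeric(shifts),
               thicknesses_mm = as.numeric(thicknesses),
               cet = est$cet, uncertainty = est$uncertainty)
  if (!is.null(out)) yaml::write_yaml(rep_, out)
  rep_
}
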