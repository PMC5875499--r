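# Coefficient of equivalent thickness (CET): material's water-equivalent
# depth-scaling factor, approximated by mass density relative to water. The
# HU -> density curve mirrors the shape of a clinical CT calibration.

#' Construct a CETTable
#' @param hu HU breakpoints (strictly increasing).
#' @param density relative density at the breakpoints (monotone).
#' @param bolusCET CET of the bolus material (default PLA, 1.119).
#' @return a \linkS4class{CETTable}.
#' @export
cetTable <- function(hu, density, bolusCET = 1.119) {
  new("CETTable", hu = hu, density = density, bolusCET = bolusCET)
}

#' Default HU to relative-density table
#'
#' Conventional calibration anchors: air -1000 HU / 0.001, lung-like -200 HU
#' / 0.8, water 0 HU / 1.000, PLA 160 HU / 1.119, cortical-like bone +800 HU
#' / 1.5, extrapolating linearly to dense bone. Replace with a
#' scanner-specific curve (e.g. from YAML via \code{\link{readCETTableYAML}})
#' for clinical use.
#'
#' @param bolusCET CET of the bolus material (default 1.119, the PLA density
#'   ratio; the measured value 1.13 can be substituted).
#' @return a \linkS4class{CETTable}.
#' @export
defaultCETTable <- function(bolusCET = 1.119) {
  cetTable(hu = c(-1024, -1000, -200, 0, 160, 800, 2000, 4000),
           density = c(0.001, 0.001, 0.8, 1.0, 1.119, 1.5, 2.2, 3.1),
           bolusCET = bolusCET)
}

#' Look up CET for HU values
#' @param table a \linkS4class{CETTable}.
#' @param hu numeric vector of HU.
#' @return relative densities (linear interpolation, clamped at the ends).
#' @export
cetAt <- function(table, hu) {
  stats::approx(table@hu, table@density, xout = hu, rule = 2)$y
}

#' Read a CET table from YAML
#'
#' Expected layout:
#' \preformatted{
#' hu: [-1000, 0, 800]
#' density: [0.001, 1.0, 1.5]
#' bolus_cet: 1.119
#' }
#'
#' @param path YAML file.
#' @return a \linkS4class{CETTable}.
#' @export
readCETTableYAML <- function(path) {
  y <- yaml::read_yaml(path)
  cetTable(hu = as.numeric(y$hu), density = as.numeric(y$density),
           bolusCET = as.numeric(y$bolus_cet %||% 1.119))
}
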