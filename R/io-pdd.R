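# Percentage-depth-dose curves travel as two-column CSV:
#   depth_mm,dose_percent

#' Read a PDD curve from CSV
#' @param path CSV file with columns \code{depth_mm,dose_percent}.
#' @return a \linkS4class{PDDCurve}.
#' @export
readPDD <- function(path) {
  df <- utils::read.csv(path)
  need <- c("depth_mm", "dose_percent")
  if (!all(need %in% names(df)))
    stop("PDD CSV must have columns depth_mm, dose_percent", call. = FALSE)
  pddCurve(depth = df$depth_mm, dose = df$dose_percent)
}

#' Write a PDD curve to CSV
#' @param curve a \linkS4class{PDDCurve}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writePDD <- function(curve, path) {
  utils::write.csv(data.frame(depth_mm = curve@depth,
                              dose_percent = curve@dose),
                   path, row.names = FALSE)
  invisible(path)
}
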