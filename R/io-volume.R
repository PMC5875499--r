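# Volume I/O. CT and dose grids are read and written as NIfTI-1 volumes
# (.nii / .nii.gz) through RNifti; the affine stores the voxel-center mapping
# so geometry round-trips. Only axis-aligned volumes with positive spacing
# are supported; oblique acquisitions must be resampled upstream.

affineFor <- function(spacing, origin) {
  M <- diag(4)
  diag(M)[1:3] <- spacing
  M[1:3, 4] <- origin + 0.5 * spacing  # center of voxel (0,0,0) in NIfTI indexing
  M
}

geometryFromAffine <- function(M) {
  R <- M[1:3, 1:3]
  if (any(abs(R[upper.tri(R)]) > 1e-6) || any(abs(R[lower.tri(R)]) > 1e-6))
    stop("volume is not axis-aligned; resample before loading", call. = FALSE)
  spacing <- diag(R)
  if (any(spacing <= 0))
    stop("negative or zero voxel spacing in affine", call. = FALSE)
  list(spacing = spacing, origin = M[1:3, 4] - 0.5 * spacing)
}

writeVolume <- function(arr, spacing, origin, path) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  img <- RNifti::`qform<-`(img, structure(affineFor(spacing, origin), code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  g <- geometryFromAffine(structure(RNifti::xform(img), dim = c(4, 4))[1:4, 1:4])
  list(arr = as.array(img), spacing = g$spacing, origin = g$origin)
}

#' Read a CT volume
#'
#' Reads a single-file NIfTI volume of Hounsfield units with its grid
#' geometry.
#'
#' @param path a .nii or .nii.gz file.
#' @return a \linkS4class{CTVolume}.
#' @export
readCT <- function(path) {
  v <- readVolume(path)
  ctVolume(array(as.integer(round(v$arr)), dim = dim(v$arr)),
           spacing = v$spacing, origin = v$origin)
}

#' Write a CT volume
#' @param ct a \linkS4class{CTVolume}.
#' @param path output .nii or .nii.gz path.
#' @return the path, invisibly.
#' @export
writeCT <- function(ct, path) {
  writeVolume(ct@voxels, ct@spacing, ct@origin, path)
}

#' Read a dose grid and resample it onto the CT grid
#'
#' The dose volume is resampled trilinearly onto the CT voxel grid and scaled
#' to percent of prescription. The file may hold absolute dose (supply
#' \code{prescription} in the same unit) or already-relative dose
#' (\code{prescription = 100}).
#'
#' @param path .nii/.nii.gz dose volume.
#' @param ct the reference \linkS4class{CTVolume}.
#' @param prescription prescription dose in the file's unit (e.g. 5040 cGy).
#' @return a \linkS4class{DoseGrid} on the CT grid, in \% of prescription.
#' @export
readDose <- function(path, ct, prescription = 100) {
  v <- readVolume(path)
  loD <- v$origin; hiD <- v$origin + dim(v$arr) * v$spacing
  loC <- ct@origin; hiC <- ct@origin + dim(ct@voxels) * ct@spacing
  if (any(pmin(hiD, hiC) <= pmax(loD, loC)))
    stop("dose grid does not overlap the CT grid", call. = FALSE)
  d <- dim(ct@voxels)
  centers <- voxelCenters(d, ct@spacing, ct@origin)
  vals <- trilinearSample(v$arr, v$origin, v$spacing, centers, fill = 0)
  doseGrid(array(pmax(vals, 0) * 100 / prescription, dim = d),
           spacing = ct@spacing, origin = ct@origin)
}

#' Write a dose grid
#' @param dose a \linkS4class{DoseGrid}.
#' @param path output .nii/.nii.gz path.
#' @return the path, invisibly.
#' @export
writeDose <- function(dose, path) {
  writeVolume(dose@dose, dose@spacing, dose@origin, path)
}

# n x 3 matrix of all voxel-center coordinates of a grid, in array order.
voxelCenters <- function(d, spacing, origin) {
  xs <- origin[1] + (seq_len(d[1]) - 0.5) * spacing[1]
  ys <- origin[2] + (seq_len(d[2]) - 0.5) * spacing[2]
  zs <- origin[3] + (seq_len(d[3]) - 0.5) * spacing[3]
  cbind(rep(xs, times = d[2] * d[3]),
        rep(rep(ys, each = d[1]), times = d[3]),
        rep(zs, each = d[1] * d[2]))
}
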