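# Structure-set I/O. Two on-disk representations are supported:
#
#  * a directory of per-structure binary masks (NIfTI, one file per
#    structure, plus structures.json naming them) -- the lossless form the
#    pipeline writes;
#  * a JSON contour set of closed planar axial polygons (the shape of a TPS
#    structure export), rasterized onto the CT grid with the even-odd rule.
#
# Contour JSON layout:
#   { "structures": { "PTV": [ { "z": 12.5, "x": [...], "y": [...] }, ... ] } }

#' Write a StructureSet as per-structure mask volumes
#' @param ss a \linkS4class{StructureSet}.
#' @param ct the CT the masks are defined on (supplies geometry).
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
writeStructures <- function(ss, ct, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- list()
  for (nm in names(ss@masks)) {
    f <- file.path(dir, paste0(gsub("[^A-Za-z0-9_.-]", "_", nm), ".nii.gz"))
    writeVolume(array(as.integer(ss@masks[[nm]]), dim = dim(ss@masks[[nm]])),
                ct@spacing, ct@origin, f)
    files[[nm]] <- basename(f)
  }
  jsonlite::write_json(list(structures = files),
                       file.path(dir, "structures.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a StructureSet
#'
#' Accepts either a mask directory written by \code{\link{writeStructures}}
#' or a contour JSON file, which is rasterized onto the CT grid.
#'
#' @param path directory or .json contour file.
#' @param ct the reference \linkS4class{CTVolume}.
#' @return a \linkS4class{StructureSet}.
#' @export
readStructures <- function(path, ct) {
  if (dir.exists(path)) {
    idx <- jsonlite::read_json(file.path(path, "structures.json"))
    masks <- list()
    for (nm in names(idx$structures)) {
      v <- readVolume(file.path(path, idx$structures[[nm]]))
      if (!identical(dim(v$arr), dim(ct@voxels)))
        stop("mask '", nm, "' shape differs from the CT grid", call. = FALSE)
      masks[[nm]] <- array(v$arr > 0.5, dim = dim(v$arr))
    }
    structureSet(masks, ct)
  } else {
    readContours(path, ct)
  }
}

#' Rasterize a JSON contour set onto a CT grid
#'
#' Each structure is a list of closed planar axial polygons. All polygons of
#' a structure landing on the same slice are combined with the even-odd rule,
#' so an inner contour cuts a hole (donut structures). Contour planes must
#' coincide with a CT slice center within half the slice spacing.
#'
#' @param path contour .json file.
#' @param ct the reference \linkS4class{CTVolume}.
#' @return a \linkS4class{StructureSet}.
#' @export
readContours <- function(path, ct) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$structures)) stop("no 'structures' entry in ", path, call. = FALSE)
  d <- dim(ct@voxels)
  zc <- ct@origin[3] + (seq_len(d[3]) - 0.5) * ct@spacing[3]
  masks <- list()
  for (nm in names(doc$structures)) {
    mask <- array(FALSE, dim = d)
    contours <- doc$structures[[nm]]
    if (is.data.frame(contours)) contours <- split(contours, seq_len(nrow(contours)))
    for (cn in contours) {
      z <- as.numeric(cn$z[[1]] %||% cn$z)
      px <- as.numeric(unlist(cn$x)); py <- as.numeric(unlist(cn$y))
      k <- which.min(abs(zc - z))
      if (abs(zc[k] - z) > ct@spacing[3] / 2 + 1e-9)
        stop("contour plane z = ", z, " of '", nm,
             "' does not match any CT slice", call. = FALSE)
      mask[, , k] <- xor(mask[, , k], rasterizePolygon(px, py, ct))
    }
    masks[[nm]] <- mask
  }
  structureSet(masks, ct)
}

# Even-odd (crossing parity) rasterization of one closed polygon onto the
# in-slice voxel-center grid. Returns a logical matrix dim (nx, ny).
rasterizePolygon <- function(px, py, ct) {
  d <- dim(ct@voxels)
  xs <- ct@origin[1] + (seq_len(d[1]) - 0.5) * ct@spacing[1]
  ys <- ct@origin[2] + (seq_len(d[2]) - 0.5) * ct@spacing[2]
  n <- length(px)
  if (n < 3) return(matrix(FALSE, d[1], d[2]))
  out <- matrix(FALSE, d[1], d[2])
  x2 <- c(px[-1], px[1]); y2 <- c(py[-1], py[1])
  for (j in seq_len(d[2])) {
    yc <- ys[j]
    # edges straddling the horizontal line y = yc (half-open to avoid
    # double-counting vertices)
    str <- (py <= yc & y2 > yc) | (y2 <= yc & py > yc)
    if (!any(str)) next
    xc <- px[str] + (yc - py[str]) * (x2[str] - px[str]) / (y2[str] - py[str])
    xc <- sort(xc)
    # fill alternate intervals
    for (m in seq(1, length(xc) - 1, by = 2))
      out[xs > xc[m] & xs <= xc[m + 1], j] <- !out[xs > xc[m] & xs <= xc[m + 1], j]
  }
  out
}
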