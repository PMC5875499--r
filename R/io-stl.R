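# Binary STL serialization (little-endian): 80-byte header, uint32 triangle
# count, then 50 bytes per triangle (normal + 3 vertices as float32, uint16
# attribute). Units are mm. Normals are recomputed from the vertex winding
# (counter-clockwise seen from outside).

#' Write a solid to binary STL
#'
#' @param solid a \linkS4class{BolusSolid} (or any object with \code{vertices}
#'   and \code{triangles} slots).
#' @param path output file.
#' @return the path, invisibly. File size is exactly 84 + 50 * n_triangles
#'   bytes.
#' @export
writeSTL <- function(solid, path) {
  V <- solid@vertices; Tr <- solid@triangles
  if (!all(is.finite(V))) stop("non-finite vertex coordinates", call. = FALSE)
  n <- nrow(Tr)
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "mertbolus binary STL (mm)"))[1:80]
  writeBin(header, con)
  writeBin(as.integer(n), con, size = 4, endian = "little")
  a <- V[Tr[, 1], , drop = FALSE]
  b <- V[Tr[, 2], , drop = FALSE]
  c_ <- V[Tr[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2))
  nrm <- nrm / ifelse(len > 0, len, 1)
  # 12 float32 per triangle, then a 2-byte attribute word
  block <- t(cbind(nrm, a, b, c_))  # 12 x n
  for (i in seq_len(n)) {
    writeBin(as.numeric(block[, i]), con, size = 4, endian = "little")
    writeBin(as.integer(0), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a binary STL file as a triangle soup
#'
#' @param path binary STL file.
#' @return a list with \code{vertices} (3n x 3, one row per triangle corner)
#'   and \code{normals} (n x 3).
#' @export
readSTL <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  n <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  verts <- matrix(0, 3 * n, 3)
  norms <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    f <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
    readBin(con, "integer", n = 1, size = 2, endian = "little")
    norms[i, ] <- f[1:3]
    verts[3 * i - 2, ] <- f[4:6]
    verts[3 * i - 1, ] <- f[7:9]
    verts[3 * i, ]     <- f[10:12]
  }
  list(vertices = verts, normals = norms)
}
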