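# Shared numerical helpers: trilinear sampling on regular voxel grids,
# bilinear sampling on the design plane, small vector utilities.
#
# Grid convention (used everywhere in the package): voxel grids are stored as
# R arrays indexed [i, j, k] along patient axes (x, y, z); the center of voxel
# (i, j, k) (1-based) sits at origin + (c(i, j, k) - 0.5) * spacing, so the
# volume occupies the half-open box [origin, origin + dim * spacing).

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Trilinear sampling of a 3D array at physical coordinates
#'
#' @param arr numeric 3D array.
#' @param origin,spacing grid geometry (mm), length-3 each.
#' @param pts n x 3 matrix of physical points (mm).
#' @param fill value returned for points outside the volume extent.
#' @return numeric vector of length n.
#' @keywords internal
#' @noRd
trilinearSample <- function(arr, origin, spacing, pts, fill = 0) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  d <- dim(arr)
  n <- nrow(pts)
  # fractional 1-based center index
  g <- cbind((pts[, 1] - origin[1]) / spacing[1] + 0.5,
             (pts[, 2] - origin[2]) / spacing[2] + 0.5,
             (pts[, 3] - origin[3]) / spacing[3] + 0.5)
  inside <- g[, 1] >= 0.5 & g[, 1] <= d[1] + 0.5 &
            g[, 2] >= 0.5 & g[, 2] <= d[2] + 0.5 &
            g[, 3] >= 0.5 & g[, 3] <= d[3] + 0.5
  out <- rep(fill, n)
  if (!any(inside)) return(out)
  gi <- g[inside, , drop = FALSE]
  # clamp to the interpolable core; the outer half-voxel band gets edge values
  for (a in 1:3) gi[, a] <- pmin(pmax(gi[, a], 1), d[a])
  i0 <- pmin(pmax(floor(gi[, 1]), 1), d[1] - 1L)
  j0 <- pmin(pmax(floor(gi[, 2]), 1), d[2] - 1L)
  k0 <- pmin(pmax(floor(gi[, 3]), 1), d[3] - 1L)
  fx <- gi[, 1] - i0; fy <- gi[, 2] - j0; fz <- gi[, 3] - k0
  v000 <- arr[cbind(i0,     j0,     k0)]
  v100 <- arr[cbind(i0 + 1, j0,     k0)]
  v010 <- arr[cbind(i0,     j0 + 1, k0)]
  v110 <- arr[cbind(i0 + 1, j0 + 1, k0)]
  v001 <- arr[cbind(i0,     j0,     k0 + 1)]
  v101 <- arr[cbind(i0 + 1, j0,     k0 + 1)]
  v011 <- arr[cbind(i0,     j0 + 1, k0 + 1)]
  v111 <- arr[cbind(i0 + 1, j0 + 1, k0 + 1)]
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  out[inside] <- c0 * (1 - fz) + c1 * fz
  out
}

# Bilinear sampling of a 2D matrix given axis coordinate vectors (regular).
bilinearSample <- function(mat, ucoords, vcoords, u, v, fill = 0) {
  du <- ucoords[2] - ucoords[1]
  dv <- vcoords[2] - vcoords[1]
  gi <- (u - ucoords[1]) / du + 1
  gj <- (v - vcoords[1]) / dv + 1
  d <- dim(mat)
  inside <- gi >= 1 & gi <= d[1] & gj >= 1 & gj <= d[2]
  out <- rep(fill, length(u))
  if (!any(inside)) return(out)
  gi <- gi[inside]; gj <- gj[inside]
  i0 <- pmin(pmax(floor(gi), 1), d[1] - 1L)
  j0 <- pmin(pmax(floor(gj), 1), d[2] - 1L)
  fx <- gi - i0; fy <- gj - j0
  out[inside] <-
    mat[cbind(i0,     j0)]     * (1 - fx) * (1 - fy) +
    mat[cbind(i0 + 1, j0)]     * fx       * (1 - fy) +
    mat[cbind(i0,     j0 + 1)] * (1 - fx) * fy +
    mat[cbind(i0 + 1, j0 + 1)] * fx       * fy
  out
}

# Intersection of a ray origin + s * dir with the axis-aligned box
# [lo, hi]; returns c(smin, smax) or NULL if the ray misses the box.
rayBoxRange <- function(origin, dir, lo, hi) {
  smin <- -Inf; smax <- Inf
  for (a in 1:3) {
    if (abs(dir[a]) < 1e-12) {
      if (origin[a] < lo[a] || origin[a] > hi[a]) return(NULL)
    } else {
      t1 <- (lo[a] - origin[a]) / dir[a]
      t2 <- (hi[a] - origin[a]) / dir[a]
      smin <- max(smin, min(t1, t2))
      smax <- min(smax, max(t1, t2))
    }
  }
  if (smin > smax) return(NULL)
  c(max(smin, 0), smax)
}

normalize3 <- function(v) v / sqrt(sum(v^2))

# Exact Euclidean distance (mm) from every TRUE cell of `mask` to the nearest
# FALSE cell, on a regular 2D grid. Small grids only; brute force in chunks.
maskEdgeDistance <- function(mask, spacing) {
  d <- dim(mask)
  out <- matrix(0, d[1], d[2])
  idxT <- which(mask, arr.ind = TRUE)
  idxF <- which(!mask, arr.ind = TRUE)
  if (nrow(idxT) == 0) return(out)
  if (nrow(idxF) == 0) { out[mask] <- Inf; return(out) }
  xF <- idxF[, 1] * spacing; yF <- idxF[, 2] * spacing
  step <- max(1L, floor(2e6 / nrow(idxF)))
  res <- numeric(nrow(idxT))
  for (s in seq(1L, nrow(idxT), by = step)) {
    e <- min(s + step - 1L, nrow(idxT))
    dx <- outer(idxT[s:e, 1] * spacing, xF, "-")
    dy <- outer(idxT[s:e, 2] * spacing, yF, "-")
    res[s:e] <- sqrt(apply(dx * dx + dy * dy, 1, min))
  }
  out[idxT] <- res
  out
}

# Binary dilation of a 2D mask by a Euclidean disk of radius r (mm);
# strict = TRUE uses the open disk (distance < r), matching the
# regional-smoothing neighborhood rule.
dilateMask <- function(mask, r, spacing, strict = FALSE) {
  nr <- ceiling(r / spacing)
  d <- dim(mask)
  out <- matrix(FALSE, d[1], d[2])
  for (di in -nr:nr) for (dj in -nr:nr) {
    rd <- sqrt(di^2 + dj^2) * spacing
    if (if (strict) rd >= r else rd > r) next
    si <- max(1, 1 - di):min(d[1], d[1] - di)
    sj <- max(1, 1 - dj):min(d[2], d[2] - dj)
    out[si + di, sj + dj] <- out[si + di, sj + dj] | mask[si, sj]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
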