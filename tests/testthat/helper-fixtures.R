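# Shared fixtures, built in code. Small grids keep the suite fast; the
# full-size study geometry is exercised in the acceptance tests.

# A homogeneous water slab with air above: side mm wide/deep, entrance at
# z = 0, beam along +z.
waterSlabCT <- function(side = 100, spacing = 2, airAbove = 10) {
  d <- c(round(side / spacing), round(side / spacing),
         round((side + airAbove) / spacing))
  origin <- c(-side / 2, -side / 2, -airAbove)
  zs <- origin[3] + (seq_len(d[3]) - 0.5) * spacing
  hu <- array(-1000L, dim = d)
  body <- array(rep(zs >= 0, each = d[1] * d[2]), dim = d)
  hu[body] <- 0L
  ct <- ctVolume(hu, spacing = rep(spacing, 3), origin = origin)
  list(ct = ct, body = body)
}

# Box mask in mm coordinates on a CT grid.
boxMask <- function(ct, xr, yr, zr) {
  d <- dim(voxels(ct))
  sp <- gridSpacing(ct); o <- gridOrigin(ct)
  xs <- o[1] + (seq_len(d[1]) - 0.5) * sp[1]
  ys <- o[2] + (seq_len(d[2]) - 0.5) * sp[2]
  zs <- o[3] + (seq_len(d[3]) - 0.5) * sp[3]
  outer(outer(xs >= xr[1] & xs <= xr[2], ys >= yr[1] & ys <= yr[2], "&"),
        zs >= zr[1] & zs <= zr[2], "&")
}

# Synthetic dose grid from a depth function dose(z) on a water-slab CT.
depthDoseGrid <- function(ct, f) {
  d <- dim(voxels(ct))
  zs <- gridOrigin(ct)[3] + (seq_len(d[3]) - 0.5) * gridSpacing(ct)[3]
  doseGrid(array(rep(pmax(f(zs), 0), each = d[1] * d[2]), dim = d),
           spacing = gridSpacing(ct), origin = gridOrigin(ct))
}

# Independent point-in-polygon test (winding-free, even-odd ray casting),
# used as the rasterization oracle.
pointInPolygonOracle <- function(x, y, px, py) {
  n <- length(px)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    cross <- (py[i] > y) != (py[j] > y)
    xin <- x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i]
    inside <- xor(inside, cross & xin)
    j <- i
  }
  inside
}

# Direct (unvectorized) evaluation of the two regional-smoothing modes,
# the independent oracle for smoothRegion().
smoothOracle <- function(values, regionP, SF, mode, spacing,
                         qmask = NULL) {
  d <- dim(values)
  if (is.null(qmask)) {
    qmask <- matrix(FALSE, d[1], d[2])
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      if (!regionP[i, j]) next
      for (a in seq_len(d[1])) for (b in seq_len(d[2])) {
        r <- sqrt((a - i)^2 + (b - j)^2) * spacing
        if (r < SF) qmask[a, b] <- TRUE
      }
    }
    qmask <- qmask & !regionP
  }
  out <- values
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    if (!regionP[i, j]) next
    num <- 0; den <- 0
    for (a in seq_len(d[1])) for (b in seq_len(d[2])) {
      if (!qmask[a, b] || (a == i && b == j)) next
      r <- sqrt((a - i)^2 + (b - j)^2) * spacing
      if (r >= SF) next
      w <- exp(-r^2 / (2 * SF^2))
      num <- num + w * values[a, b]
      den <- den + w
    }
    out[i, j] <- if (mode == 1) num / (1 + den) else
      (values[i, j] + num) / (1 + den)
  }
  out
}
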