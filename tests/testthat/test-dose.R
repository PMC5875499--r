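test_that("depth-dose model hits its calibration points", {
  for (E in c(6, 9, 12, 16)) {
    m <- pddModel(E)
    expect_equal(pddEval(m, m$zmax), 100)
    expect_equal(pddEval(m, m$R50), 50, tolerance = 0.1)
    expect_equal(pddEval(m, 2 * m$Rp), 2, tolerance = 0.2)
    # monotone non-increasing beyond zmax
    zs <- seq(m$zmax, 2 * m$Rp, by = 0.25)
    expect_true(all(diff(pddEval(m, zs)) <= 1e-9))
  }
})

test_that("on-axis surrogate dose matches the depth-dose curve in water", {
  slab <- waterSlabCT(side = 100, spacing = 2)
  ss <- structureSet(list(BODY = slab$body), slab$ct)
  beam <- beamSpec(12, 10, isocenter = c(0, 0, 0))
  d <- computeDose(slab$ct, ss, beam)
  zs <- seq(2, 70, by = 2)
  prof <- mertbolus:::trilinearSample(doseArray(d), gridOrigin(d),
                                      gridSpacing(d), cbind(0, 0, zs))
  expect_lt(max(abs(prof - pddEval(12, zs))), 1.0)
})

test_that("uniform bolus shifts the depth dose by CET x thickness", {
  slab <- waterSlabCT(side = 100, spacing = 2)
  ss <- structureSet(list(BODY = slab$body), slab$ct)
  beam <- beamSpec(12, 10, isocenter = c(0, 0, 0))
  plane <- buildSbtPlane(beam)
  t0 <- matrix(10, length(plane@u), length(plane@v))
  d <- computeDose(slab$ct, ss, beam, thickness = t0, plane = plane)
  # the falloff moves shallower by 1.119 * 10 mm
  s90 <- isodoseDistalDepth(c(0, 0, -1000), c(0, 0, 1), d, 90)
  expect_equal(s90 - 1000, pddInvert(12, 90) - 11.19, tolerance = 0.5)
})

test_that("dose far outside the field edge is negligible", {
  slab <- waterSlabCT(side = 140, spacing = 2.5)
  ss <- structureSet(list(BODY = slab$body), slab$ct)
  beam <- beamSpec(12, 6, isocenter = c(0, 0, 0))  # 60 mm field
  d <- computeDose(slab$ct, ss, beam, fanMargin = 45)
  v <- mertbolus:::trilinearSample(doseArray(d), gridOrigin(d),
                                   gridSpacing(d),
                                   cbind(60, 0, c(10, 20, 30)))
  expect_true(all(v < 1))  # 30 mm beyond the 30 mm half field
})

test_that("adding bolus never increases dose beyond the buildup along a ray", {
  slab <- waterSlabCT(side = 80, spacing = 2)
  ss <- structureSet(list(BODY = slab$body), slab$ct)
  beam <- beamSpec(9, 6, isocenter = c(0, 0, 0))
  plane <- buildSbtPlane(beam)
  d0 <- computeDose(slab$ct, ss, beam)
  tb <- matrix(6, length(plane@u), length(plane@v))
  db <- computeDose(slab$ct, ss, beam, thickness = tb, plane = plane)
  zs <- seq(pddModel(9)$zmax, 60, by = 1)
  p0 <- mertbolus:::trilinearSample(doseArray(d0), gridOrigin(d0),
                                    gridSpacing(d0), cbind(0, 0, zs))
  pb <- mertbolus:::trilinearSample(doseArray(db), gridOrigin(db),
                                    gridSpacing(db), cbind(0, 0, zs))
  expect_true(all(pb <= p0 + 0.3))
})

test_that("heterogeneities scale the surrogate depth dose", {
  # an air slab shifts the falloff deeper by ~ its water-equivalent deficit
  slab <- waterSlabCT(side = 80, spacing = 2)
  hu <- voxels(slab$ct)
  air <- boxMask(slab$ct, c(-40, 40), c(-40, 40), c(10, 20))
  hu[air] <- -1000L
  ctAir <- ctVolume(hu, gridSpacing(slab$ct), gridOrigin(slab$ct))
  ss <- structureSet(list(BODY = slab$body), ctAir)
  beam <- beamSpec(12, 10, isocenter = c(0, 0, 0))
  d <- computeDose(ctAir, ss, beam)
  s90 <- isodoseDistalDepth(c(0, 0, -1000), c(0, 0, 1), d, 90)
  expect_equal(s90 - 1000, pddInvert(12, 90) + 10, tolerance = 1.5)
})

test_that("gamma of identical planes is zero with a 100% pass rate", {
  set.seed(5)
  A <- matrix(80 + 20 * runif(900), 30, 30)
  g <- gamma2d(A, A, spacing = 2.5)
  expect_equal(max(g$gamma), 0)
  expect_equal(g$passRate, 100)
})

test_that("a uniform 3% offset sits exactly on the gamma boundary", {
  A <- matrix(100, 30, 30)
  B <- A + 3  # 3% of the global maximum
  g <- gamma2d(B, A, spacing = 2.5, doseCrit = 3, distCrit = 5)
  expect_equal(unname(g$gamma[15, 15]), 1, tolerance = 1e-9)
  expect_equal(g$passRate, 100)  # gamma <= 1 passes
})

test_that("a 5 mm shift of a linear gradient passes the 5 mm distance
           criterion", {
  xs <- seq(0, 72.5, by = 2.5)
  A <- outer(xs, rep(1, 30)) + 30          # linear gradient along rows
  B <- outer(xs + 5, rep(1, 30)) + 30      # shifted by 2 cells = 5 mm
  g <- gamma2d(B, A, spacing = 2.5, doseCrit = 3, distCrit = 5)
  inner <- g$gamma[3:28, ]
  expect_true(all(inner <= 1 + 1e-9))
})

test_that("gamma matches an exhaustive-search oracle on random planes", {
  set.seed(21)
  n <- 50
  base <- outer(seq(100, 60, length.out = n), rep(1, n))
  A <- base + matrix(rnorm(n * n, sd = 1), n, n)
  B <- base + matrix(rnorm(n * n, sd = 1), n, n)
  g <- gamma2d(A, B, spacing = 2.5, doseCrit = 3, distCrit = 5)
  dd <- 0.03 * max(B)
  oracle <- function(i, j) {
    best <- Inf
    for (a in max(1, i - 6):min(n, i + 6))
      for (b in max(1, j - 6):min(n, j + 6)) {
        r <- sqrt((a - i)^2 + (b - j)^2) * 2.5
        if (r > 15) next
        best <- min(best, (r / 5)^2 + ((A[i, j] - B[a, b]) / dd)^2)
      }
    sqrt(best)
  }
  for (pt in list(c(1, 1), c(7, 30), c(25, 25), c(50, 13), c(33, 2))) {
    expect_equal(unname(g$gamma[pt[1], pt[2]]), oracle(pt[1], pt[2]),
                 tolerance = 1e-12)
  }
  expect_error(gamma2d(A, matrix(0, n, n), spacing = 2.5), "all-zero")
})

test_that("the optional scatter term raises dose under locally thin bolus", {
  slab <- waterSlabCT(side = 80, spacing = 2)
  ss <- structureSet(list(BODY = slab$body), slab$ct)
  beam <- beamSpec(12, 6, isocenter = c(0, 0, 0))
  plane <- buildSbtPlane(beam)
  th <- matrix(12, length(plane@u), length(plane@v))
  ic <- (length(plane@u) + 1) / 2
  th[(ic - 1):(ic + 1), (ic - 1):(ic + 1)] <- 2  # a thin valley
  d0 <- computeDose(slab$ct, ss, beam, thickness = th, plane = plane)
  d1 <- computeDose(slab$ct, ss, beam, thickness = th, plane = plane,
                    scatterGain = 0.5)
  v0 <- mertbolus:::trilinearSample(doseArray(d0), gridOrigin(d0),
                                    gridSpacing(d0), cbind(0, 0, 10))
  v1 <- mertbolus:::trilinearSample(doseArray(d1), gridOrigin(d1),
                                    gridSpacing(d1), cbind(0, 0, 10))
  expect_gt(v1, v0)
})
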