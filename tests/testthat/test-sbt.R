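# The CET line integral and the thickness-shift computation. Closed-form
# cases: 10 mm of water = 10 mm; 5 mm bone (CET 1.5) + 5 mm water = 12.5 mm;
# gaps divide by the bolus CET 1.119 (10 / 1.119 = 8.937,
# 12.5 / 1.119 = 11.171).

boneSlabCT <- function() {
  # bone slab only under x < 0 so x > 0 rays stay in pure water
  slab <- waterSlabCT(side = 80, spacing = 2)
  hu <- voxels(slab$ct)
  bone <- boxMask(slab$ct, c(-40, 0), c(-40, 40), c(20, 25))
  hu[bone] <- 800L
  list(ct = ctVolume(hu, gridSpacing(slab$ct), gridOrigin(slab$ct)),
       body = slab$body)
}

test_that("CET line integrals reproduce closed forms", {
  tab <- defaultCETTable()
  slab <- waterSlabCT(side = 80, spacing = 2)
  src <- c(0, 0, -1000); dz <- c(0, 0, 1)
  expect_equal(cetLineIntegral(src, dz, slab$ct, tab, 1005, 1015), 10,
               tolerance = 1e-9)
  expect_identical(cetLineIntegral(src, dz, slab$ct, tab, 1010, 1010), 0)

  bs <- boneSlabCT()
  # 20..25 mm is bone (CET 1.5): 5 bone + 5 water from z = 20 to 30
  src <- c(-20, 0, -1000)
  got <- cetLineIntegral(src, dz, bs$ct, tab, 1020, 1030)
  expect_equal(got, 12.5, tolerance = 0.8)  # voxelized interface blurs
  # fine-step brute-force oracle agrees much tighter
  fine <- cetLineIntegral(src, dz, bs$ct, tab, 1020, 1030, step = 0.01)
  expect_equal(got, fine, tolerance = 0.05)
})

test_that("the integral is additive over subintervals and rejects
           out-of-volume ranges", {
  bs <- boneSlabCT()
  tab <- defaultCETTable()
  # smooth (water-only) path: additivity is exact to numerical precision
  src <- c(13, -7, -1000); dz <- mertbolus:::normalize3(c(0.005, 0.01, 1))
  whole <- cetLineIntegral(src, dz, bs$ct, tab, 1010, 1060)
  parts <- cetLineIntegral(src, dz, bs$ct, tab, 1010, 1023.3) +
           cetLineIntegral(src, dz, bs$ct, tab, 1023.3, 1060)
  expect_lt(abs(whole - parts), 1e-6)
  # across a material interface the midpoint rule is additive to O(step)
  srcB <- c(-20, 0, -1000)
  wholeB <- cetLineIntegral(srcB, dz, bs$ct, tab, 1000, 1060)
  partsB <- cetLineIntegral(srcB, dz, bs$ct, tab, 1000, 1023.3) +
            cetLineIntegral(srcB, dz, bs$ct, tab, 1023.3, 1060)
  expect_lt(abs(wholeB - partsB), 0.01)
  expect_error(cetLineIntegral(src, dz, bs$ct, tab, 100, 2000),
               "outside the CT")
})

test_that("integrals match the 0.01 mm brute-force oracle on random
           heterogeneous rays", {
  set.seed(101)
  bs <- boneSlabCT()
  tab <- defaultCETTable()
  for (k in 1:10) {
    src <- c(runif(1, -30, -10), runif(1, -15, 15), -1000)
    dir <- mertbolus:::normalize3(c(runif(2, -0.009, 0.009), 1))
    a <- 1000 + runif(1, 0, 20)
    b <- a + runif(1, 5, 40)
    got <- cetLineIntegral(src, dir, bs$ct, tab, a, b)
    oracle <- cetLineIntegral(src, dir, bs$ct, tab, a, b, step = 0.01)
    expect_lt(abs(got - oracle), 0.05)
  }
})

test_that("computeSBT equals gap / CET_bolus on homogeneous water and is
           linear in the gap", {
  tab <- defaultCETTable()
  slab <- waterSlabCT(side = 80, spacing = 2)
  beam <- beamSpec(12, 4, isocenter = c(0, 0, 0))
  plane <- buildSbtPlane(beam, margin = 0, spacing = 2)
  rays <- planeRays(beam, plane)
  nu <- length(plane@u)
  # constructed depths: distal PTV at s = 1020, isodose at s = 1030
  ptvD <- matrix(1020, nu, nu)
  isoD <- matrix(1030, nu, nu)
  g <- computeSBT(plane, rays, ptvD, isoD, slab$ct, tab)
  expect_true(all(abs(sbtValues(g) - 10 / 1.119) < 0.1))
  expect_equal(sbtValues(g)[11, 11], 8.937, tolerance = 1e-2)

  g2 <- computeSBT(plane, rays, ptvD, matrix(1040, nu, nu), slab$ct, tab)
  expect_equal(sbtValues(g2), 2 * sbtValues(g), tolerance = 1e-6)

  # zero gap -> zero; negative gap -> negative SBT
  g0 <- computeSBT(plane, rays, ptvD, ptvD, slab$ct, tab)
  expect_true(all(sbtValues(g0) == 0))
  gn <- computeSBT(plane, rays, ptvD, matrix(1010, nu, nu), slab$ct, tab)
  expect_equal(sbtValues(gn), -sbtValues(g), tolerance = 1e-6)
})

test_that("a heterogeneous gap divides its water-equivalent length by the
           bolus CET", {
  tab <- defaultCETTable()
  bs <- boneSlabCT()
  beam <- beamSpec(12, 4, isocenter = c(0, 0, 0))
  plane <- buildSbtPlane(beam, margin = 0, spacing = 2)
  rays <- planeRays(beam, plane)
  nu <- length(plane@u)
  g <- computeSBT(plane, rays, matrix(1020, nu, nu), matrix(1030, nu, nu),
                  bs$ct, tab)
  iNeg <- which(plane@u == -10)  # a ray on the bone side, away from the edge
  jc <- (nu + 1) / 2
  expect_equal(sbtValues(g)[iNeg, jc], 11.171, tolerance = 0.1)
})

test_that("rays without an isodose crossing are flagged and filled from
           neighbors", {
  tab <- defaultCETTable()
  slab <- waterSlabCT(side = 80, spacing = 2)
  beam <- beamSpec(12, 4, isocenter = c(0, 0, 0))
  plane <- buildSbtPlane(beam, margin = 0, spacing = 2)
  rays <- planeRays(beam, plane)
  nu <- length(plane@u)
  ptvD <- matrix(1020, nu, nu)
  isoD <- matrix(1030, nu, nu)
  isoD[5, 5] <- NA
  g <- computeSBT(plane, rays, ptvD, isoD, slab$ct, tab)
  expect_equal(attr(g, "flagged"), 1)
  expect_equal(sbtValues(g)[5, 5], 10 / 1.119, tolerance = 0.1)
})

test_that("applySBT clamps at zero and reports the clamp count", {
  th <- matrix(5, 4, 4)
  sbt <- matrix(-8, 4, 4); sbt[1, 1] <- 0; sbt[2, 2] <- 3
  out <- applySBT(th, sbt)
  expect_equal(out[1, 1], 5)
  expect_equal(out[2, 2], 8)
  expect_true(all(out[-c(1, 6)] == 0))
  expect_equal(attr(out, "clamped"), 14)

  # zero shift is the identity; positive shift from zero equals the shift
  z <- matrix(0, 4, 4)
  expect_equal(unclass(applySBT(th, z)), th, ignore_attr = TRUE)
  pos <- matrix(2.5, 4, 4)
  expect_equal(unclass(applySBT(z, pos)), pos, ignore_attr = TRUE)
})
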