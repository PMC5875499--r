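# The regional smoothing formula, hand-evaluated for the fixture below:
# p with neighbors {8 at r = 2.5 mm, 4 at r = 5 mm}, SF = 5, mode 1:
#   w1 = exp(-2.5^2 / 50) = 0.88250, w2 = exp(-25 / 50) = 0.60653
#   (8 w1 + 4 w2) / (1 + w1 + w2) = 9.48613 / 2.48903 = 3.81118

test_that("mode-1 smoothing reproduces the hand-evaluated weighted mean", {
  v <- matrix(0, 9, 9)
  region <- matrix(FALSE, 9, 9); region[5, 5] <- TRUE
  v[6, 5] <- 8    # r = 2.5 mm at 2.5 mm spacing
  v[7, 5] <- 4    # r = 5.0 mm
  qm <- matrix(FALSE, 9, 9); qm[6, 5] <- TRUE; qm[7, 5] <- TRUE
  out <- smoothRegion(v, region, SF = 5.0001, mode = 1, spacing = 2.5,
                      qmask = qm)
  w1 <- exp(-2.5^2 / (2 * 5.0001^2)); w2 <- exp(-5^2 / (2 * 5.0001^2))
  expect_equal(out[5, 5], (8 * w1 + 4 * w2) / (1 + w1 + w2),
               tolerance = 1e-12)
  expect_equal(out[5, 5], 3.811, tolerance = 2e-3)
  # all other cells untouched
  out[5, 5] <- v[5, 5]
  expect_equal(out, v)
})

test_that("both smoothing modes match direct summation on random grids", {
  set.seed(11)
  for (rep in 1:4) {
    v <- matrix(rnorm(20 * 20, sd = 5), 20, 20)
    region <- matrix(runif(400) < 0.15, 20, 20)
    if (!any(region)) next
    for (mode in 1:2) {
      got <- smoothRegion(v, region, SF = 7.5, mode = mode, spacing = 2.5)
      want <- smoothOracle(v, region, SF = 7.5, mode = mode, spacing = 2.5)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("mode 2 preserves constant fields; mode 1 shrinks them", {
  v <- matrix(3.7, 15, 15)
  region <- matrix(FALSE, 15, 15); region[5:8, 5:8] <- TRUE
  out2 <- smoothRegion(v, region, SF = 10, mode = 2, spacing = 2.5)
  expect_equal(out2, v, tolerance = 1e-12)
  out1 <- smoothRegion(v, region, SF = 10, mode = 1, spacing = 2.5)
  expect_true(all(out1[region] < 3.7))
  expect_true(all(out1[region] > 0))
})

test_that("smoothing output is bounded by the input magnitudes and a point
           with no neighbors follows the documented convention", {
  set.seed(3)
  v <- matrix(rnorm(100, sd = 4), 10, 10)
  region <- matrix(runif(100) < 0.2, 10, 10)
  out <- smoothRegion(v, region, SF = 5, mode = 2, spacing = 2.5)
  expect_true(max(abs(out)) <= max(abs(v)) + 1e-12)

  # isolated p with empty q-set: mode 1 -> 0, mode 2 -> unchanged
  v0 <- matrix(0, 9, 9); v0[5, 5] <- 6
  reg <- matrix(FALSE, 9, 9); reg[5, 5] <- TRUE
  qe <- matrix(FALSE, 9, 9)
  expect_equal(smoothRegion(v0, reg, 5, 1, 2.5, qmask = qe)[5, 5], 0)
  expect_equal(smoothRegion(v0, reg, 5, 2, 2.5, qmask = qe)[5, 5], 6)
})

test_that("hot-spot smoothing is a no-op on empty regions and damps spikes", {
  v <- matrix(0, 15, 15); v[8, 8] <- 10
  expect_identical(hotspotSmoothing(v, matrix(FALSE, 15, 15), 10,
                                    spacing = 2.5), v)
  region <- matrix(FALSE, 15, 15); region[8, 8] <- TRUE
  out <- hotspotSmoothing(v, region, SF = 10, spacing = 2.5)
  expect_lt(abs(out[8, 8]), 10)
  # whole-grid constant region shrinks toward zero by sum w / (1 + sum w)
  vc <- matrix(2, 15, 15)
  all_ <- matrix(TRUE, 15, 15)
  outc <- hotspotSmoothing(vc, all_, SF = 10, spacing = 2.5)
  expect_true(all(outc < 2))
})

test_that("coverage smoothing keeps region values, bounds the annulus and
           preserves non-positivity", {
  v <- matrix(0, 21, 21)
  under <- matrix(FALSE, 21, 21); under[9:13, 9:13] <- TRUE
  v[under] <- -5
  out <- coverageSmoothing(v, under, SF = 10, spacing = 2.5)
  expect_equal(out[under], v[under])          # retained
  annulus <- mertbolus:::dilateMask(under, 10, 2.5, strict = TRUE) & !under
  expect_true(all(out[annulus] > -5 & out[annulus] < 0))
  expect_true(all(out <= 0))
  expect_identical(coverageSmoothing(v, matrix(FALSE, 21, 21), 10,
                                     spacing = 2.5), v)
})

test_that("irregularity smoothing flags steps, spares smooth hills and
           leaves constants alone", {
  vconst <- matrix(4, 20, 20)
  expect_identical(irregularitySmoothing(vconst, spacing = 2.5),
                   structure(vconst, passes = 0L))

  step <- matrix(0, 20, 20); step[11:20, ] <- 10
  out <- irregularitySmoothing(step, SF = 10, spacing = 2.5)
  expect_lt(max(gradientMagnitude(unclass(out), 2.5)),
            max(gradientMagnitude(step, 2.5)))

  xs <- seq(-25, 25, length.out = 21)
  hill <- outer(xs, xs, function(a, b) 8 * exp(-(a^2 + b^2) / 400))
  g <- gradientMagnitude(hill, 2.5)
  expect_lt(mean(g > 2 * mean(g)), 0.05)
})

test_that("margin kernel satisfies its defining properties", {
  k <- marginKernel(sigma = 10)
  expect_equal(kerfMA(k, 0), 1)
  expect_equal(kernelK1(k), 10 * sqrt(-2 * log(0.01)))
  expect_equal(kerfMA(k, kernelK1(k)), 0.01, tolerance = 1e-12)
  expect_equal(defaultSigma(beamSpec(9, 10)), sqrt(90))
})

test_that("margin adjustment applies the two branches with the right
           factors", {
  # disk PTV projection on a 41x41 grid at 2.5 mm, border 10 mm
  n <- 41
  idx <- seq_len(n) - (n + 1) / 2
  r <- sqrt(outer(idx^2, idx^2, "+")) * 2.5
  ptv <- r <= 40
  k <- marginKernel(sigma = 10, borderWidth = 10)
  vpos <- matrix(10, n, n)
  outp <- marginAdjustment(vpos, ptv, k, spacing = 2.5)
  ed <- mertbolus:::maskEdgeDistance(ptv, 2.5)
  border <- ptv & ed <= 10
  # positive branch: factor in [0, 1) -> never flips sign, always reduced
  expect_true(all(outp[border] >= 0 & outp[border] < 10))
  expect_equal(outp[!border], vpos[!border])
  # inner-boundary cells (r_pm ~ 0): factor ~ 1 - kerf(K1) = 0.99
  inner <- ptv & ed > 10 & ed <= 10 + 2.6
  expect_equal(mean(outp[border & mertbolus:::dilateMask(inner, 3, 2.5)]),
               9.9, tolerance = 0.15)

  vneg <- matrix(-10, n, n)
  outn <- marginAdjustment(vneg, ptv, k, spacing = 2.5)
  # negative branch: magnitude grows, factor in (1, 2]
  expect_true(all(outn[border] <= -10 & outn[border] >= -20))
})

test_that("a small sigma zeroes positive SBT at the far border
           (KerfMA(0) = 1 boundary case)", {
  n <- 41
  idx <- seq_len(n) - (n + 1) / 2
  r <- sqrt(outer(idx^2, idx^2, "+")) * 2.5
  ptv <- r <= 40
  k <- marginKernel(sigma = 2, borderWidth = 10)  # K1 = 6.07 mm < border
  v <- matrix(10, n, n)
  out <- marginAdjustment(v, ptv, k, spacing = 2.5)
  ed <- mertbolus:::maskEdgeDistance(ptv, 2.5)
  far <- ptv & ed <= 2.5   # r_pm >= border - 2.5 > K1 -> factor 0
  expect_true(all(abs(out[far]) < 1e-9))
})

test_that("extrusion copies boundary values radially and is idempotent", {
  n <- 41
  idx <- seq_len(n) - (n + 1) / 2
  rr <- sqrt(outer(idx^2, idx^2, "+")) * 2.5
  ptv <- rr <= 30
  ap <- matrix(TRUE, n, n)
  ap[rr > 47.5] <- FALSE
  # constant boundary value extrudes everywhere outside
  v <- matrix(0, n, n); v[ptv] <- 7
  out <- extrudeOutside(v, ptv, ap, spacing = 2.5)
  expect_true(all(out[ap & !ptv] == 7))
  expect_true(all(out[!ap] == 0))
  expect_identical(extrudeOutside(out, ptv, ap, spacing = 2.5), out)

  # cos(theta) boundary pattern is preserved angularly
  th <- atan2(outer(rep(1, n), idx), outer(idx, rep(1, n)))
  v2 <- matrix(0, n, n); v2[ptv] <- cos(th[ptv])
  out2 <- extrudeOutside(v2, ptv, ap, spacing = 2.5)
  sel <- (ap & !ptv) & rr < 45
  expect_lt(max(abs(out2[sel] - cos(th[sel]))), 0.25)
})

test_that("all five operators are no-ops on empty regions", {
  v <- matrix(rnorm(441), 21, 21)
  e <- matrix(FALSE, 21, 21)
  expect_identical(hotspotSmoothing(v, e, 10, spacing = 2.5), v)
  expect_identical(coverageSmoothing(v, e, 10, spacing = 2.5), v)
  k <- marginKernel(10)
  expect_identical(marginAdjustment(v, e, k, spacing = 2.5), v)
})
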