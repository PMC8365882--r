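# Free-knot spline centerline fitting, curvature/torsion, distance
# metric and shape index against closed forms.

test_that("a smooth cubic curve is fitted to high accuracy with exact-in-u reproduction", {
  # a curve that is cubic in the chord-length parameter (straight line with
  # nonuniform sampling) is reproduced to machine precision with 0 knots
  t <- seq(0, 1, length.out = 25)
  lin <- cbind(10 * t^2 + t, 0, 0)  # monotone, collinear
  mLin <- fitCenterline(lin, maxInteriorKnots = 4)
  expect_lt(mLin@rms, 1e-9)
  expect_equal(mLin@nInteriorKnots, 0L)
  # a generic cubic space curve is not polynomial in chord length; the fit
  # still tracks it closely and its curvature matches a finite-difference
  # oracle on dense exact samples
  t <- seq(0, 1, length.out = 100)
  pts <- cbind(t, 0.4 * t^3 - 0.3 * t, 0.3 * t^2)
  m <- fitCenterline(pts, maxInteriorKnots = 10, optimizeKnots = FALSE)
  expect_lt(m@rms, 1e-5)
  td <- seq(0, 1, length.out = 4001)
  dense <- cbind(td, 0.4 * td^3 - 0.3 * td, 0.3 * td^2)
  g <- coroflow:::discreteCurveGeometry(dense, td)
  sDense <- c(0, cumsum(coroflow:::rowNorm(diff(dense))))
  ct <- curvatureTorsion(m, nStations = 20)
  kOracle <- approx(sDense[g$idx], g$kappa, xout = ct$s)$y
  expect_lt(max(abs(ct$kappa - kOracle)) / max(kOracle), 0.02)
})

test_that("collinear points give a straight fit with masked torsion", {
  pts <- cbind(seq(0, 30, length.out = 20), 0, 0)
  m <- fitCenterline(pts)
  ct <- curvatureTorsion(m, nStations = 20)
  expect_lt(max(ct$kappa), 1e-6)
  expect_true(ct$torsionUndefined)
  expect_equal(ct$tauMean, 0)
  expect_equal(distanceMetric(m), 1, tolerance = 1e-9)
  expect_error(fitCenterline(pts[c(1, 1:19), ]), "duplicate")
})

test_that("helix and circle fits recover closed-form curvature and torsion", {
  hel <- makeCenterline("helix", list(a = 3, b = 4), resolution = 7)  # ~200 pts
  m <- fitCenterline(hel@points, maxInteriorKnots = 20, optimizeKnots = FALSE)
  ct <- curvatureTorsion(m)
  expect_lt(max(abs(ct$kappa - 0.12)) / 0.12, 0.01)   # within 1% away from ends
  expect_lt(abs(ct$kappaMean - 0.12) / 0.12, 0.02)
  expect_lt(abs(ct$tauMean - 0.16) / 0.16, 0.02)

  circ <- makeCenterline("arc", list(R = 20, angle = pi), resolution = 6)
  mc <- fitCenterline(circ@points, maxInteriorKnots = 10)
  ctc <- curvatureTorsion(mc)
  expect_equal(ctc$kappaMean, 0.05, tolerance = 1e-3)
  expect_lt(abs(ctc$tauMean), 1e-4)
})

test_that("distance metric matches closed forms", {
  # straight
  m <- fitCenterline(cbind(seq(0, 25, length.out = 12), 0, 0))
  expect_equal(distanceMetric(m), 1, tolerance = 1e-9)
  # half circle: pi/2
  circ <- makeCenterline("arc", list(R = 20, angle = pi), resolution = 10)
  mc <- fitCenterline(circ@points, maxInteriorKnots = 15, optimizeKnots = FALSE)
  expect_equal(distanceMetric(mc), pi / 2, tolerance = 1e-6)
  # one helix turn: sqrt(a^2+b^2)/b = 1.25
  hel <- makeCenterline("helix", list(a = 3, b = 4), resolution = 8)
  mh <- fitCenterline(hel@points, maxInteriorKnots = 15, optimizeKnots = FALSE)
  expect_equal(distanceMetric(mh), 1.25, tolerance = 1e-5)
  # the analytic curve gives the same value
  expect_equal(distanceMetric(hel), 1.25, tolerance = 1e-9)
})

test_that("shape index is 1 for circular and e for elliptical straight tubes", {
  clPts <- cbind(seq(0, 30, length.out = 40), 0, 0)
  m <- fitCenterline(clPts, maxInteriorKnots = 3)
  tubeC <- straightTube(length = 30, radius = 2, nCirc = 48, nAxial = 20)
  siC <- shapeIndex(tubeSurface(tubeC), m, nStations = 50)
  expect_equal(siC$siMean, 1, tolerance = 1e-2)
  expect_true(all(siC$si > 0 & siC$si <= 1, na.rm = TRUE))
  tubeE <- straightTube(length = 30, radius = 2, ecc = 0.5, nCirc = 48, nAxial = 20)
  siE <- shapeIndex(tubeSurface(tubeE), m, nStations = 50)
  expect_equal(siE$siMean, 0.5, tolerance = 1e-2)
})

test_that("morphometry is rigid-motion invariant and scales correctly", {
  hel <- makeCenterline("helix", list(a = 3, b = 4), resolution = 4)
  tube <- makeTube(tubeSpec(hel, radius = 1.2, nCirc = 24, nAxial = 30, nRadial = 2))
  m <- fitCenterline(hel@points, maxInteriorKnots = 8, optimizeKnots = FALSE)
  si0 <- shapeIndex(tubeSurface(tube), m, nStations = 30)
  set.seed(21)
  R <- randomRotation(); shift <- c(4, -7, 2)
  ptsR <- sweep(hel@points %*% t(R), 2, -shift)
  mR <- fitCenterline(ptsR, maxInteriorKnots = 8, optimizeKnots = FALSE)
  surfR <- rotateSurface(tubeSurface(tube), R, shift)
  siR <- shapeIndex(surfR, mR, nStations = 30)
  expect_equal(siR$siMean, si0$siMean, tolerance = 1e-6)
  ct0 <- curvatureTorsion(m); ctR <- curvatureTorsion(mR)
  expect_equal(ctR$kappaMean, ct0$kappaMean, tolerance = 1e-9)
  expect_equal(ctR$tauMean, ct0$tauMean, tolerance = 1e-9)
  expect_equal(distanceMetric(mR), distanceMetric(m), tolerance = 1e-9)
  # uniform scaling: kappa, tau scale by 1/c; DM unchanged
  c0 <- 2.5
  mS <- fitCenterline(hel@points * c0, maxInteriorKnots = 8, optimizeKnots = FALSE)
  ctS <- curvatureTorsion(mS)
  expect_equal(ctS$kappaMean, ct0$kappaMean / c0, tolerance = 1e-6)
  expect_equal(ctS$tauMean, ct0$tauMean / c0, tolerance = 1e-6)
  expect_equal(distanceMetric(mS), distanceMetric(m), tolerance = 1e-9)
  expect_gte(distanceMetric(mS), 1 - 1e-9)
})

test_that("coordinate noise of 0.05 mm moves mean curvature by < 10% (smoothing)", {
  hel <- makeCenterline("helix", list(a = 3, b = 4), resolution = 3)
  m0 <- fitCenterline(hel@points, maxInteriorKnots = 6)
  set.seed(17)
  noisy <- hel@points + matrix(rnorm(length(hel@points), sd = 0.05), ncol = 3)
  mN <- fitCenterline(noisy, maxInteriorKnots = 6)
  k0 <- curvatureTorsion(m0)$kappaMean
  kN <- curvatureTorsion(mN)$kappaMean
  expect_lt(abs(kN - k0) / k0, 0.10)
})
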