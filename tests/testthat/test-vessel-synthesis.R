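# Vessel, flow and cohort synthesis against closed forms and
# finite-difference oracles.

test_that("centerline closed forms match an independent finite-difference oracle", {
  cases <- list(
    list(kind = "straight", params = list(length = 50), kappa = 0, tau = 0,
         L = 50, chord = 50),
    list(kind = "helix", params = list(a = 3, b = 4), kappa = 3 / 25, tau = 4 / 25,
         L = 2 * pi * 5, chord = 2 * pi * 4),
    list(kind = "arc", params = list(R = 20, angle = pi), kappa = 0.05, tau = 0,
         L = pi * 20, chord = 40))
  for (cs in cases) {
    cl <- makeCenterline(cs$kind, cs$params, resolution = 4)
    expect_equal(cl@exact$kappa(cl@u[5]), cs$kappa, tolerance = 1e-12)
    expect_equal(cl@exact$tau(cl@u[5]), cs$tau, tolerance = 1e-12)
    expect_equal(cl@exact$length, cs$L, tolerance = 1e-12)
    expect_equal(cl@exact$chord, cs$chord, tolerance = 1e-12)
    # independent oracle: finite differences on the dense samples
    g <- coroflow:::discreteCurveGeometry(cl@points, cl@u)
    expect_lt(max(abs(g$kappa - cs$kappa)), 1e-4 * max(1, cs$kappa) + 1e-6)
    if (cs$kappa > 0)
      expect_lt(max(abs(g$tau - cs$tau), na.rm = TRUE), 1e-3)
    # polyline arc length approximates the closed form
    expect_equal(max(cl@s), cs$L, tolerance = 1e-4)
  }
  expect_error(makeCenterline("helix", list(a = -1, b = 2)), "a > 0")
})

test_that("tube meshes converge to closed-form volume and area at order ~2", {
  cl <- makeCenterline("straight", list(length = 20))
  exactV <- pi * 4 * 20
  exactA <- 2 * pi * 2 * 20 + 2 * pi * 4
  errs <- sapply(c(8, 16, 32), function(nc) {
    tb <- makeTube(tubeSpec(cl, radius = 2, nCirc = nc, nAxial = 8, nRadial = 3))
    c(abs(sum(tetVolumes(tubeVolume(tb))) - exactV),
      abs(sum(triangleAreas(tubeSurface(tb))) - exactA))
  })
  ordV <- log2(errs[1, 1:2] / errs[1, 2:3])
  ordA <- log2(errs[2, 1:2] / errs[2, 2:3])
  expect_true(all(ordV >= 1.8))
  expect_true(all(ordA >= 1.8))
})

# offset of each lateral node from its section centroid (an independent
# radial direction, not derived from the stored normals)
radialOffset <- function(surf, nLat) {
  st <- nodeStation(surf)[seq_len(nLat)]
  off <- matrix(0, nLat, 3)
  for (s0 in unique(st)) {
    i <- which(st == s0)
    ctr <- colMeans(vertices(surf)[i, , drop = FALSE])
    off[i, ] <- sweep(vertices(surf)[i, , drop = FALSE], 2, ctr)
  }
  off
}

test_that("elliptical sections honor the eccentricity and normals point outward", {
  tube <- straightTube(radius = 2, ecc = 0.5, nCirc = 24)
  surf <- tubeSurface(tube)
  # first-station ring: min/max node distance from the axis = eccentricity
  ring <- seq_len(24)
  r <- sqrt(rowSums(vertices(surf)[ring, 2:3, drop = FALSE]^2))
  expect_equal(min(r) / max(r), 0.5, tolerance = 1e-9)

  # helix tube: lateral normals point away from the local section centroid
  hel <- makeTube(tubeSpec(makeCenterline("helix", list(a = 8, b = 4)),
                           radius = 1.5, nCirc = 12, nAxial = 20, nRadial = 2))
  hs <- tubeSurface(hel)
  nLat <- 20 * 12
  dots <- rowSums(surfaceNormals(hs)[seq_len(nLat), ] *
                  coroflow:::rowUnit(radialOffset(hs, nLat)))
  expect_true(all(dots > 0))
})

test_that("tube self-intersection risk is rejected", {
  cl <- makeCenterline("arc", list(R = 3, angle = pi))  # kappa = 1/3
  expect_error(makeTube(tubeSpec(cl, radius = 3.5, nCirc = 8, nAxial = 6, nRadial = 2)),
               "self-intersect")
})

test_that("analytic flow fields carry the expected helicity density and vorticity", {
  tube <- straightTube(length = 10, radius = 2)
  vm <- tubeVolume(tube)
  # plug + swirl: v.omega = 2*Omega*U everywhere
  vf <- sampleFlow(flowSpec("plug", U = 1, omega = 2, waveform = unitWaveform,
                            nTimes = 4), vm)
  hd <- rowSums(vf@velocity[, , 1] * vf@vorticityExact[, , 1])
  expect_equal(unname(range(hd)), c(4, 4), tolerance = 1e-12)
  # parabolic, no swirl: v.omega = 0, |omega| = 2*U*rho/R^2
  vf2 <- sampleFlow(flowSpec("parabolic", U = 0.5, omega = 0,
                             waveform = unitWaveform, nTimes = 4), vm)
  hd2 <- rowSums(vf2@velocity[, , 1] * vf2@vorticityExact[, , 1])
  expect_lt(max(abs(hd2)), 1e-12)
  R_m <- vm@rlocal * 1e-3
  expect_equal(sqrt(rowSums(vf2@vorticityExact[, , 1]^2)),
               2 * 0.5 * (vm@rho * 1e-3) / R_m^2, tolerance = 1e-9)
  # zero waveform: zero field
  vf3 <- sampleFlow(flowSpec("plug", U = 1, omega = 2,
                             waveform = function(t) rep(0, length(t)),
                             nTimes = 4), vm)
  expect_equal(max(abs(vf3@velocity)), 0)
})

test_that("analytic WSS matches the Poiseuille closed form and reverses with the waveform", {
  tube <- straightTube(length = 10, radius = 2)
  surf <- tubeSurface(tube)
  sf <- sampleWSS(flowSpec("parabolic", U = 0.1, omega = 0,
                           waveform = unitWaveform, nTimes = 4, mu = 0.0035), surf)
  mag <- sqrt(rowSums(sf@wss[, , 2]^2))
  expect_equal(unname(range(mag)), rep(2 * 0.0035 * 0.1 / 0.002, 2), tolerance = 1e-12)
  # no swirl -> purely axial at lateral nodes
  ax <- surf@frame$axis
  expect_lt(max(abs(sf@wss[, , 1] - rowSums(sf@wss[, , 1] * ax) * ax)), 1e-15)
  # sinusoidal waveform: reversal at half cycle, zero cycle-mean
  T <- 0.8
  sf2 <- sampleWSS(flowSpec("parabolic", U = 0.1,
                            waveform = function(t) sin(2 * pi * t / T),
                            period = T, nTimes = 8), surf)
  i4 <- which.min(abs(sf2@times - T / 4))
  i34 <- which.min(abs(sf2@times - 3 * T / 4))
  expect_equal(sf2@wss[, , i34], -sf2@wss[, , i4], tolerance = 1e-12)
  m <- coroflow:::integralVec(sf2)
  expect_lt(max(abs(m)), 1e-12)
  # plug profile has no analytic wall shear
  expect_error(sampleWSS(flowSpec("plug", U = 0.1), surf), "parabolic")
})

test_that("waveform summaries use the trapezoidal cycle mean", {
  T <- 0.8
  # constant
  wfc <- flowWaveform(c(0, T / 2), c(5e-5, 5e-5), period = T)
  s <- waveformSummary(wfc)
  expect_equal(s$mean, 5e-5)
  expect_equal(s$peak, 5e-5)
  expect_equal(s$peak_to_peak, 0)
  # closed-form sinusoid: mean 3, peak 5, ptp 4
  t <- seq(0, T, length.out = 201)
  wfs <- flowWaveform(t, 3 + 2 * sin(2 * pi * t / T), period = T)
  s2 <- waveformSummary(wfs)
  expect_equal(s2$mean, 3, tolerance = 1e-4)
  expect_equal(s2$peak, 5, tolerance = 1e-3)
  expect_equal(s2$peak_to_peak, 4, tolerance = 1e-3)
  # two samples
  s3 <- waveformSummary(flowWaveform(c(0, 1), c(2, 4)))
  expect_equal(s3$peak, 4)
  expect_equal(s3$peak_to_peak, 2)
  expect_error(flowWaveform(0, 1), "at least 2")
})

test_that("cohort generation hits target medians and is seed-reproducible", {
  des <- defaultCohortDesign()
  big <- makeCohort(des, nPerGroup = 1000, seed = 11)
  hLAD <- big[big$species == "human" & big$vessel_type == "LAD", ]
  expect_lt(abs(median(hLAD$osi) - 5e-4) / 5e-4, 0.10)
  sLAD <- big[big$species == "swine" & big$vessel_type == "LAD", ]
  expect_lt(abs(median(sLAD$osi) - 2.3e-3) / 2.3e-3, 0.10)
  # zero dispersion collapses to the median
  d0 <- des; d0$sdlog <- 0
  flat <- makeCohort(d0, nPerGroup = 3, seed = 1)
  expect_equal(unname(range(flat$tawss)), c(1.5, 1.5))
  # determinism
  expect_identical(makeCohort(des, nPerGroup = 5, seed = 99),
                   makeCohort(des, nPerGroup = 5, seed = 99))
  # invalid medians rejected
  dbad <- des; dbad$median[dbad$descriptor == "tawss"] <- -1
  expect_error(makeCohort(dbad, nPerGroup = 3, seed = 1), "positive-only")
})
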