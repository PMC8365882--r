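# Vorticity reconstruction, LNH and bulk helicity descriptors against
# closed forms.

tubeH <- straightTube(length = 10, radius = 2, nCirc = 12, nAxial = 8, nRadial = 3)
vmH <- tubeVolume(tubeH)

# build a velocity field from a function of node coordinates [mm -> m/s]
fieldFromFun <- function(mesh, vfun, nt = 2, period = 1) {
  n <- nrow(vertices(mesh))
  v1 <- t(apply(vertices(mesh), 1, vfun))
  vel <- array(0, dim = c(n, 3, nt))
  for (ti in seq_len(nt)) vel[, , ti] <- v1
  volumeField(mesh, (0:(nt - 1)) * period / nt, period, vel)
}

test_that("discrete curl reproduces linear fields exactly", {
  # uniform translation -> zero vorticity
  fU <- fieldFromFun(vmH, function(p) c(0.3, -0.1, 0.2))
  expect_lt(max(abs(vorticity(fU))), 1e-12)
  # rigid rotation about z at Omega = 2 -> omega = (0, 0, 4); coordinates mm -> m
  fR <- fieldFromFun(vmH, function(p) 2 * c(-p[2], p[1], 0) * 1e-3)
  vo <- vorticity(fR)
  ii <- interiorNodes(vmH)
  expect_equal(unname(range(vo[ii, 3, 1])), c(4, 4), tolerance = 1e-9)
  expect_lt(max(abs(vo[ii, 1:2, 1])), 1e-9)
  # simple shear v = (3*y, 0, 0) -> omega = (0, 0, -3)
  fS <- fieldFromFun(vmH, function(p) c(3 * p[2] * 1e-3, 0, 0))
  vo2 <- vorticity(fS)
  expect_equal(unname(range(vo2[ii, 3, 1])), c(-3, -3), tolerance = 1e-9)
})

test_that("discrete curl converges to the closed-form vorticity (order >= 0.9)", {
  cl <- makeCenterline("straight", list(length = 20))
  errs <- sapply(1:2, function(lev) {
    tb <- makeTube(tubeSpec(cl, radius = 2, nCirc = 10 * 2^(lev - 1),
                            nAxial = 8 * 2^(lev - 1), nRadial = 3 * 2^(lev - 1)))
    vm <- tubeVolume(tb)
    vf <- sampleFlow(flowSpec("parabolic", U = 0.5, omega = 0,
                              waveform = unitWaveform, nTimes = 2), vm)
    ii <- interiorNodes(vm)
    max(abs(vorticity(vf)[ii, , 1] - vf@vorticityExact[ii, , 1]))
  })
  expect_gte(log2(errs[1] / errs[2]), 0.9)
})

test_that("LNH hits the cosine limits and vanishes for Poiseuille flow", {
  # parallel / antiparallel: use the plug+swirl field where v || omega on the axis
  vf <- sampleFlow(flowSpec("plug", U = 1, omega = 2, waveform = unitWaveform,
                            nTimes = 4), vmH)
  l <- lnh(vf, vf@vorticityExact)
  expect_true(all(l$lnh[l$mask] > 0))          # sign of Omega*U
  axisNodes <- which(vmH@rhoNorm < 1e-12)
  expect_equal(unname(range(l$lnh[axisNodes, ])), c(1, 1), tolerance = 1e-12)
  expect_true(all(l$cycleAverage >= -1 & l$cycleAverage <= 1))
  # antiparallel on the axis when the swirl is reversed
  vfN <- sampleFlow(flowSpec("plug", U = 1, omega = -2, waveform = unitWaveform,
                             nTimes = 4), vmH)
  lN <- lnh(vfN, vfN@vorticityExact)
  expect_equal(unname(range(lN$lnh[axisNodes, ])), c(-1, -1), tolerance = 1e-12)
  # Poiseuille: v perpendicular to omega everywhere
  vfP <- sampleFlow(flowSpec("parabolic", U = 0.4, omega = 0,
                             waveform = unitWaveform, nTimes = 4), vmH)
  lP <- lnh(vfP, vfP@vorticityExact)
  expect_lt(max(abs(lP$lnh)), 1e-9)
})

test_that("bulk helicity of swirling plug flow equals 2*Omega*U; Poiseuille is zero", {
  vf <- sampleFlow(flowSpec("plug", U = 1, omega = 2, waveform = unitWaveform,
                            nTimes = 4), vmH)
  hs <- helicitySummary(vf)  # discrete vorticity: linear field, curl exact
  expect_equal(hs@h1, 4, tolerance = 1e-9)
  expect_equal(hs@h2, 4, tolerance = 1e-9)
  expect_equal(hs@h3, 1, tolerance = 1e-12)
  expect_equal(hs@h4, 1, tolerance = 1e-12)
  # mesh refinement keeps the value within 1%
  tbF <- straightTube(length = 10, radius = 2, nCirc = 24, nAxial = 16, nRadial = 6)
  vfF <- sampleFlow(flowSpec("plug", U = 1, omega = 2, waveform = unitWaveform,
                             nTimes = 4), tubeVolume(tbF))
  hsF <- helicitySummary(vfF)
  expect_lt(abs(hsF@h1 - 4) / 4, 0.01)

  vfP <- sampleFlow(flowSpec("parabolic", U = 0.4, omega = 0,
                             waveform = unitWaveform, nTimes = 4), vmH)
  hsP <- helicitySummary(vfP, vfP@vorticityExact)
  expect_equal(hsP@h1, 0, tolerance = 1e-12)
  expect_equal(hsP@h2, 0, tolerance = 1e-12)
  expect_true(is.na(hsP@h3) && is.na(hsP@h4))
})

test_that("counter-rotating halves cancel h1 but not h2", {
  nA <- 22
  tb <- straightTube(length = 20, radius = 2, nCirc = 10, nAxial = nA, nRadial = 3)
  vm <- tubeVolume(tb)
  sgn <- ifelse(nodeStation(vm) < 10, 1, -1)
  U <- 1; Om <- 2
  n <- nrow(vertices(vm))
  vel <- array(0, dim = c(n, 3, 2))
  vort <- array(0, dim = c(n, 3, 2))
  base <- U * vm@axis + sgn * Om * (vm@rho * 1e-3) * vm@azimuth
  wb <- 2 * Om * sgn * vm@axis
  for (ti in 1:2) { vel[, , ti] <- base; vort[, , ti] <- wb }
  vf <- volumeField(vm, c(0, 0.5), 1, vel)
  hs <- helicitySummary(vf, vort)
  expect_lt(abs(hs@h1), 1e-9)
  # cells straddling the sign change average to ~0: one slab of nA-1
  expect_gt(hs@h2, 4 * (nA - 2) / (nA - 1) - 1e-9)
  expect_lte(hs@h2, 4 + 1e-9)
  expect_lt(abs(hs@h3), 1e-9)
  expect_lt(abs(hs@h4), 1e-9)
})

test_that("helicity identities and swirl-flip antisymmetry hold for random fields", {
  n <- nrow(vertices(vmH))
  nt <- 6
  for (seed in 1:6) {
    set.seed(seed)
    vel <- array(rnorm(n * 3 * nt, sd = 0.3), dim = c(n, 3, nt))
    vf <- volumeField(vmH, (0:(nt - 1)) / nt, 1, vel)
    hs <- helicitySummary(vf)
    expect_gte(hs@h2, abs(hs@h1) - 1e-12)
    if (!is.na(hs@h3)) {
      expect_equal(hs@h3, hs@h1 / hs@h2, tolerance = 1e-12)
      expect_equal(hs@h4, abs(hs@h3), tolerance = 1e-12)
    }
  }
  # flipping the swirl sign flips h1, h3 and LNH; h2, h4 unchanged
  fw <- function(om) sampleFlow(flowSpec("plug", U = 1, omega = om,
                                         nTimes = 6), vmH)
  a <- helicitySummary(fw(3)); b <- helicitySummary(fw(-3))
  expect_equal(a@h1, -b@h1, tolerance = 1e-12)
  expect_equal(a@h3, -b@h3, tolerance = 1e-12)
  expect_equal(a@h2, b@h2, tolerance = 1e-12)
  expect_equal(a@h4, b@h4, tolerance = 1e-12)
  la <- lnh(fw(3)); lb <- lnh(fw(-3))
  expect_equal(la$lnh, -lb$lnh, tolerance = 1e-12)
})
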