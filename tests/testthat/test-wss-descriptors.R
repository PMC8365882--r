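# Near-wall WSS descriptor maps: closed-form examples, an independent
# quadrature oracle, identities and invariances.

# independent oracle: evaluate the OSI formula with adaptive quadrature
# on the piecewise-linear interpolant of a sampled vector history
osiOracle <- function(times, vecs, period) {
  t2 <- c(times, period)
  v2 <- rbind(vecs, vecs[1, ])
  fa <- approxfun(t2, sqrt(rowSums(v2^2)))
  ia <- integrate(fa, 0, period, rel.tol = 1e-10, subdivisions = 500)$value
  iv <- sapply(1:3, function(k)
    integrate(function(t) approx(t2, v2[, k], xout = t)$y, 0, period,
              rel.tol = 1e-10, subdivisions = 500)$value)
  0.5 * (1 - sqrt(sum(iv^2)) / ia)
}

surfDefault <- straightTube(length = 10, radius = 2, nCirc = 12, nAxial = 6)
surf <- tubeSurface(surfDefault)

test_that("TAWSS reproduces constant, rectified-sine and zero signals", {
  fC <- uniformWSSField(surf, function(t) c(1.5, 0, 0), nt = 8)
  expect_equal(unname(range(descriptorValues(tawss(fC)))), c(1.5, 1.5))
  # dense sine: cycle mean of |sin| = 2/pi
  fS <- uniformWSSField(surf, function(t) c(sin(2 * pi * t), 0, 0), nt = 512)
  expect_equal(descriptorValues(tawss(fS))[1], 2 / pi, tolerance = 1e-4)
  fZ <- uniformWSSField(surf, function(t) c(0, 0, 0), nt = 8)
  expect_equal(max(descriptorValues(tawss(fZ))), 0)
})

test_that("trapezoidal quadrature is second order (error drops ~4x when nt doubles)", {
  errAt <- function(nt) {
    f <- uniformWSSField(surf, function(t) c(sin(2 * pi * t), 0, 0), nt = nt)
    abs(descriptorValues(tawss(f))[1] - 2 / pi)
  }
  ratio <- errAt(64) / errAt(128)
  expect_gt(ratio, 3.2)
  expect_lt(ratio, 4.8)
})

test_that("OSI limits: 0 for fixed direction, 0.5 for zero temporal mean", {
  fFixed <- uniformWSSField(surf, function(t) c(1 + 0.5 * sin(2 * pi * t), 0, 0), nt = 32)
  expect_equal(unname(range(descriptorValues(osi(fFixed)))), c(0, 0))
  fRev <- uniformWSSField(surf, function(t) c(ifelse(t < 0.5, 1, -1), 0, 0), nt = 32)
  expect_equal(unname(range(descriptorValues(osi(fRev)))), c(0.5, 0.5))
  # all-zero node is masked, not an error
  fZ <- uniformWSSField(surf, function(t) c(0, 0, 0), nt = 8)
  expect_false(any(descriptorMask(osi(fZ))))
})

test_that("OSI of a square-wave transverse component matches the quadrature oracle", {
  nt <- 256
  times <- (0:(nt - 1)) / nt
  vecs <- cbind(1, ifelse(times < 0.5, 1, -1), 0)
  n <- nrow(vertices(surf))
  w <- array(0, dim = c(n, 3, nt))
  for (ti in seq_len(nt)) w[, , ti] <- matrix(vecs[ti, ], n, 3, byrow = TRUE)
  f <- surfaceField(surf, times, 1, w)
  expect_equal(descriptorValues(osi(f))[1], osiOracle(times, vecs, 1),
               tolerance = 1e-6)
})

test_that("RRT: steady limit, first-form arithmetic, and form equivalence", {
  fSteady <- uniformWSSField(surf, function(t) c(1, 0, 0), nt = 8)
  expect_equal(unname(range(descriptorValues(rrt(fSteady)))), c(1, 1))
  # constructed signal with TAWSS = 2 and OSI = 0.25:
  # |mean| = (1 - 2*OSI)*TAWSS = 1 -> RRT = 1 (equal-duration 3 and -1)
  fC <- uniformWSSField(surf, function(t) c(ifelse(t < 0.5, 3, -1), 0, 0), nt = 64)
  expect_equal(descriptorValues(tawss(fC))[1], 2, tolerance = 1e-12)
  expect_equal(descriptorValues(osi(fC))[1], 0.25, tolerance = 1e-12)
  expect_equal(descriptorValues(rrt(fC))[1], 1, tolerance = 1e-12)
  # identity RRT * TAWSS * (1 - 2 OSI) = 1 on a random smooth signal
  set.seed(3)
  a <- rnorm(3); b <- rnorm(3); c0 <- c(2, 0.5, 0.1)
  fR <- uniformWSSField(surf, function(t)
    c0 + a * sin(2 * pi * t) + b * cos(4 * pi * t), nt = 64)
  idn <- descriptorValues(rrt(fR)) * descriptorValues(tawss(fR)) *
    (1 - 2 * descriptorValues(osi(fR)))
  expect_equal(unname(range(idn)), c(1, 1), tolerance = 1e-9)
  # zero-mean node is masked (RRT diverges)
  fRev <- uniformWSSField(surf, function(t) c(ifelse(t < 0.5, 1, -1), 0, 0), nt = 32)
  expect_false(any(descriptorMask(rrt(fRev))))
})

test_that("transWSS: collinear history gives 0; +/-45 degree alternation gives sin(45)", {
  fCol <- uniformWSSField(surf, function(t) c(1 + 0.3 * sin(2 * pi * t), 0, 0), nt = 32)
  expect_lt(max(descriptorValues(transWSS(fCol))), 1e-12)
  # construct the alternation in each node's tangent plane: mean direction
  # along the local axis, transverse along n x axis = -azimuth
  nt <- 32
  times <- (0:(nt - 1)) / nt
  n <- nrow(vertices(surf))
  ax <- surf@frame$axis
  tr <- coroflow:::rowCross(surfaceNormals(surf), ax)
  w <- array(0, dim = c(n, 3, nt))
  sgn <- rep(c(1, -1), nt / 2)
  for (ti in seq_len(nt))
    w[, , ti] <- cos(pi / 4) * ax + sgn[ti] * sin(pi / 4) * tr
  f45 <- surfaceField(surf, times, 1, w)
  v <- descriptorValues(transWSS(f45))
  m <- descriptorMask(transWSS(f45))
  lateral <- seq_len(6 * 12)  # end-cap centers have n parallel to the axis
  expect_equal(unname(range(v[intersect(lateral, which(m))])),
               rep(sin(pi / 4), 2), tolerance = 1e-9)
})

test_that("all four maps are invariant under rigid rotation and translation", {
  set.seed(7)
  nt <- 16
  n <- nrow(vertices(surf))
  w <- array(rnorm(n * 3 * nt), dim = c(n, 3, nt))
  f <- surfaceField(surf, (0:(nt - 1)) / nt, 1, w)
  R <- randomRotation()
  fR <- rotateField(f, R, shift = c(5, -3, 2))
  for (op in list(tawss, osi, rrt, transWSS)) {
    expect_equal(descriptorValues(op(fR)), descriptorValues(op(f)),
                 tolerance = 1e-12)
  }
})

test_that("OSI bounds and TAWSS >= |mean WSS| hold for random fields (fuzz)", {
  nt <- 12
  n <- nrow(vertices(surf))
  # non-uniform strictly increasing grids starting at 0
  for (seed in 1:8) {
    set.seed(seed)
    tgrid <- c(0, sort(runif(nt - 1, 0.01, 0.98)))
    w <- array(rnorm(n * 3 * nt, sd = runif(1, 0.1, 3)), dim = c(n, 3, nt))
    f <- surfaceField(surf, tgrid, 1, w)
    o <- descriptorValues(osi(f))
    expect_true(all(o >= 0 & o <= 0.5))
    tw <- descriptorValues(tawss(f))
    meanMag <- coroflow:::rowNorm(coroflow:::integralVec(f)) / 1
    expect_true(all(tw >= meanMag - 1e-12))
  }
})

test_that("surface summaries weight by lumped node areas", {
  n <- nrow(vertices(surf))
  cMap <- new("DescriptorMap", values = rep(2.5, n), mask = rep(TRUE, n),
              name = "x", units = "")
  expect_equal(surfaceSummary(cMap, surf, "area_weighted_mean"), 2.5)
  expect_equal(surfaceSummary(cMap, surf, "area_weighted_median"), 2.5)
  # two equal-area halves valued 1 and 3 -> mean 2 (split by axial half)
  v <- ifelse(nodeStation(surf) < max(nodeStation(surf)) / 2, 1, 3)
  hMap <- new("DescriptorMap", values = v, mask = rep(TRUE, n), name = "x", units = "")
  expect_equal(surfaceSummary(hMap, surf, "area_weighted_mean"), 2, tolerance = 0.1)
  # weighted median against a brute-force sort-and-accumulate oracle
  set.seed(5)
  vv <- rexp(n)
  sMap <- new("DescriptorMap", values = vv, mask = rep(TRUE, n), name = "x", units = "")
  wts <- nodeAreas(surf)
  o <- order(vv)
  oracle <- vv[o][which(cumsum(wts[o]) >= sum(wts) / 2)[1]]
  expect_equal(surfaceSummary(sMap, surf, "area_weighted_median"), oracle)
  # empty valid set errors
  eMap <- new("DescriptorMap", values = vv, mask = rep(FALSE, n), name = "x", units = "")
  expect_error(surfaceSummary(eMap, surf), "no valid nodes")
})
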