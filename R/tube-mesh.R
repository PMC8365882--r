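# Swept-tube mesh generation: elliptical cross-sections carried along a
# centerline on a rotation-minimizing frame (RMF), triangulated laterally
# and filled with tetrahedra. RMF (double-reflection) rather than Frenet
# frames: the Frenet normal is undefined on straight segments and flips
# at inflections.

#' Specify a swept-tube geometry
#'
#' @param centerline a [ParametricCurve-class] from [makeCenterline()].
#' @param radius major semi-axis r(s) \[mm\]: scalar or function of arc
#'   length.
#' @param eccentricity minor/major semi-axis ratio e(s) in (0, 1\]:
#'   scalar or function of arc length.
#' @param nCirc circumferential resolution (>= 8).
#' @param nAxial axial stations (>= 4).
#' @param nRadial radial rings of the volume mesh (>= 2).
#' @return a list of class `TubeSpec`.
#' @export
tubeSpec <- function(centerline, radius = 2, eccentricity = 1,
                     nCirc = 24, nAxial = 40, nRadial = 5) {
  if (!is(centerline, "ParametricCurve")) stopParameter("centerline must be a ParametricCurve")
  if (nCirc < 8 || nAxial < 4 || nRadial < 2)
    stopParameter("resolution too low: need nCirc >= 8, nAxial >= 4, nRadial >= 2")
  rFun <- if (is.function(radius)) radius else function(s) rep(radius, length(s))
  eFun <- if (is.function(eccentricity)) eccentricity else function(s) rep(eccentricity, length(s))
  structure(list(centerline = centerline, rFun = rFun, eFun = eFun,
                 nCirc = as.integer(nCirc), nAxial = as.integer(nAxial),
                 nRadial = as.integer(nRadial)),
            class = "TubeSpec")
}

# Resample a curve at n stations uniform in arc length; unit tangents by
# central differences on the dense polyline.
resampleCurve <- function(curve, n) {
  s <- curve@s
  pts <- curve@points
  m <- nrow(pts)
  tg <- matrix(0, m, 3)
  tg[2:(m - 1), ] <- pts[3:m, ] - pts[1:(m - 2), ]
  tg[1, ] <- pts[2, ] - pts[1, ]
  tg[m, ] <- pts[m, ] - pts[m - 1, ]
  tg <- rowUnit(tg)
  sOut <- seq(0, max(s), length.out = n)
  C <- sapply(1:3, function(k) approx(s, pts[, k], xout = sOut)$y)
  Tg <- rowUnit(sapply(1:3, function(k) approx(s, tg[, k], xout = sOut)$y))
  list(s = sOut, C = C, Tg = Tg)
}

# Rotation-minimizing frame by the double-reflection method.
rmfFrames <- function(C, Tg) {
  n <- nrow(C)
  e <- if (abs(Tg[1, 3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  r <- e - sum(e * Tg[1, ]) * Tg[1, ]
  r <- r / sqrt(sum(r^2))
  N1 <- matrix(0, n, 3)
  N1[1, ] <- r
  for (i in 1:(n - 1)) {
    v1 <- C[i + 1, ] - C[i, ]
    c1 <- sum(v1 * v1)
    if (c1 == 0) stopGeometry("coincident consecutive stations")
    rL <- N1[i, ] - (2 / c1) * sum(v1 * N1[i, ]) * v1
    tL <- Tg[i, ] - (2 / c1) * sum(v1 * Tg[i, ]) * v1
    v2 <- Tg[i + 1, ] - tL
    c2 <- sum(v2 * v2)
    N1[i + 1, ] <- if (c2 > 1e-30) rL - (2 / c2) * sum(v2 * rL) * v2 else rL
  }
  N2 <- rowCross(Tg, N1)  # (N1, N2, Tg) right-handed: N1 x N2 = -? keep t x n1 = n2
  list(N1 = N1, N2 = N2)
}

# Dompierre-style prism -> 3 tets split with diagonals through the
# smallest global index, guaranteeing conforming faces between slabs.
prismRotations <- matrix(c(
  1, 2, 3, 4, 5, 6,
  2, 3, 1, 5, 6, 4,
  3, 1, 2, 6, 4, 5,
  4, 6, 5, 1, 3, 2,
  5, 4, 6, 2, 1, 3,
  6, 5, 4, 3, 2, 1), nrow = 6, byrow = TRUE)

splitPrisms <- function(P) {
  np <- nrow(P)
  k <- max.col(-P, ties.method = "first")  # position of min index
  Q <- matrix(0L, np, 6)
  for (j in 1:6) Q[, j] <- P[cbind(seq_len(np), prismRotations[k, j])]
  useA <- pmin(Q[, 2], Q[, 6]) < pmin(Q[, 3], Q[, 5])
  tets <- matrix(0L, 3 * np, 4)
  iA <- which(useA); iB <- which(!useA)
  if (length(iA)) {
    tets[3 * (iA - 1) + 1, ] <- Q[iA, c(1, 2, 3, 6), drop = FALSE]
    tets[3 * (iA - 1) + 2, ] <- Q[iA, c(1, 2, 6, 5), drop = FALSE]
    tets[3 * (iA - 1) + 3, ] <- Q[iA, c(1, 5, 6, 4), drop = FALSE]
  }
  if (length(iB)) {
    tets[3 * (iB - 1) + 1, ] <- Q[iB, c(1, 2, 3, 5), drop = FALSE]
    tets[3 * (iB - 1) + 2, ] <- Q[iB, c(1, 5, 3, 6), drop = FALSE]
    tets[3 * (iB - 1) + 3, ] <- Q[iB, c(1, 5, 6, 4), drop = FALSE]
  }
  tets
}

orientTets <- function(vertices, tets) {
  a <- vertices[tets[, 1], , drop = FALSE]
  b <- vertices[tets[, 2], , drop = FALSE] - a
  c3 <- vertices[tets[, 3], , drop = FALSE] - a
  d <- vertices[tets[, 4], , drop = FALSE] - a
  vol <- rowSums(b * rowCross(c3, d))
  flip <- vol < 0
  if (any(flip)) tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]
  if (any(abs(vol) < 1e-14)) stopGeometry("degenerate (zero-volume) tetrahedron generated")
  tets
}

#' Generate watertight surface and tetrahedral volume meshes of a tube
#'
#' Sweeps elliptical cross-sections (semi-axes `r(s)` and `e(s)*r(s)`)
#' along the centerline on a rotation-minimizing frame. The lateral
#' surface is closed by end-cap fans; triangle winding is
#' counter-clockwise viewed from outside and per-node normals are the
#' analytic ellipse normals (end-cap centers carry the +/- axis). Every
#' node records its axial station, in-plane radius and local
#' axis/azimuth directions, which the flow synthesizer consumes.
#'
#' A self-intersection guard rejects specs where
#' `max(kappa) * max(semi-axis) >= 1` (the swept sections would fold).
#'
#' @param spec a `TubeSpec` from [tubeSpec()].
#' @return a [TubeMesh-class] with `surface` and `volume` slots.
#' @examples
#' tube <- makeTube(tubeSpec(makeCenterline("straight", list(length = 20)),
#'                           radius = 2, nCirc = 12, nAxial = 8, nRadial = 3))
#' sum(tetVolumes(tubeVolume(tube)))  # -> pi * 4 * 20 as resolution grows
#' @export
makeTube <- function(spec) {
  if (!inherits(spec, "TubeSpec")) stopParameter("spec must come from tubeSpec()")
  cl <- spec$centerline
  nA <- spec$nAxial; nC <- spec$nCirc; nR <- spec$nRadial
  rs <- resampleCurve(cl, nA)
  A <- spec$rFun(rs$s)          # major semi-axis
  ecc <- spec$eFun(rs$s)
  if (any(A <= 0)) stopParameter("radius profile must be positive")
  if (any(ecc <= 0 | ecc > 1)) stopParameter("eccentricity must be in (0, 1]")
  B <- ecc * A

  # self-intersection guard
  kap <- if (!is.null(cl@exact)) max(cl@exact$kappa(cl@u)) else {
    g <- discreteCurveGeometry(cl@points, cl@u); max(g$kappa)
  }
  if (kap * max(A, B) >= 1)
    stopGeometry("tube self-intersects: max curvature %.3g 1/mm x max semi-axis %.3g mm >= 1",
                 kap, max(A, B))

  fr <- rmfFrames(rs$C, rs$Tg)
  theta <- 2 * pi * (0:(nC - 1)) / nC
  ct <- cos(theta); st <- sin(theta)

  # ---- surface ----------------------------------------------------------
  nLat <- nA * nC
  sv <- matrix(0, nLat + 2, 3)
  sn <- matrix(0, nLat + 2, 3)
  sstat <- numeric(nLat + 2)
  sax <- matrix(0, nLat + 2, 3)
  saz <- matrix(0, nLat + 2, 3)
  srl <- numeric(nLat + 2)
  for (i in seq_len(nA)) {
    idx <- (i - 1) * nC + seq_len(nC)
    off <- outer(A[i] * ct, fr$N1[i, ]) + outer(B[i] * st, fr$N2[i, ])
    sv[idx, ] <- matrix(rs$C[i, ], nC, 3, byrow = TRUE) + off
    # ellipse outward normal ~ (cos/A) n1 + (sin/B) n2
    nrm <- outer(ct / A[i], fr$N1[i, ]) + outer(st / B[i], fr$N2[i, ])
    sn[idx, ] <- rowUnit(nrm)
    sstat[idx] <- rs$s[i]
    sax[idx, ] <- matrix(rs$Tg[i, ], nC, 3, byrow = TRUE)
    saz[idx, ] <- rowUnit(outer(-A[i] * st, fr$N1[i, ]) + outer(B[i] * ct, fr$N2[i, ]))
    srl[idx] <- rowNorm(off)
  }
  c0 <- nLat + 1L; c1 <- nLat + 2L
  sv[c0, ] <- rs$C[1, ]; sv[c1, ] <- rs$C[nA, ]
  sn[c0, ] <- -rs$Tg[1, ]; sn[c1, ] <- rs$Tg[nA, ]
  sstat[c0] <- rs$s[1]; sstat[c1] <- rs$s[nA]
  sax[c0, ] <- rs$Tg[1, ]; sax[c1, ] <- rs$Tg[nA, ]
  srl[c0] <- A[1] * ecc[1]; srl[c1] <- A[nA] * ecc[nA]

  jn <- c(2:nC, 1)  # next angle index
  tri <- vector("list", 3)
  # lateral quads: (A, B, C) + (A, C, D) with outward winding
  iAx <- rep(1:(nA - 1), each = nC)
  jj <- rep(seq_len(nC), nA - 1)
  a <- (iAx - 1) * nC + jj
  b <- (iAx - 1) * nC + jn[jj]
  cc <- iAx * nC + jn[jj]
  d <- iAx * nC + jj
  tri[[1]] <- rbind(cbind(a, b, cc), cbind(a, cc, d))
  # caps
  j <- seq_len(nC)
  tri[[2]] <- cbind(rep(c0, nC), jn[j], j)
  tri[[3]] <- cbind(rep(c1, nC), (nA - 1) * nC + j, (nA - 1) * nC + jn[j])
  triangles <- do.call(rbind, tri)
  dimnames(triangles) <- NULL
  storage.mode(triangles) <- "integer"

  surface <- new("TriSurface", vertices = sv, triangles = triangles,
                 normals = sn, station = sstat,
                 frame = list(axis = sax, azimuth = saz, rlocal = srl))

  # ---- volume -----------------------------------------------------------
  nps <- 1L + nR * nC  # nodes per station: center + rings
  nV <- nA * nps
  vv <- matrix(0, nV, 3)
  vstat <- numeric(nV); vrho <- numeric(nV); vrhon <- numeric(nV)
  vrl <- numeric(nV)
  vax <- matrix(0, nV, 3); vaz <- matrix(0, nV, 3)
  for (i in seq_len(nA)) {
    base <- (i - 1L) * nps
    vv[base + 1L, ] <- rs$C[i, ]
    vstat[base + 1L] <- rs$s[i]
    vax[base + 1L, ] <- rs$Tg[i, ]
    vrl[base + 1L] <- B[i]
    unitOff <- outer(A[i] * ct, fr$N1[i, ]) + outer(B[i] * st, fr$N2[i, ])
    azim <- rowUnit(outer(-A[i] * st, fr$N1[i, ]) + outer(B[i] * ct, fr$N2[i, ]))
    rl <- rowNorm(unitOff)
    for (k in seq_len(nR)) {
      f <- k / nR
      idx <- base + 1L + (k - 1L) * nC + seq_len(nC)
      vv[idx, ] <- matrix(rs$C[i, ], nC, 3, byrow = TRUE) + f * unitOff
      vstat[idx] <- rs$s[i]
      vrho[idx] <- f * rl
      vrhon[idx] <- f
      vrl[idx] <- rl
      vax[idx, ] <- matrix(rs$Tg[i, ], nC, 3, byrow = TRUE)
      vaz[idx, ] <- azim
    }
  }

  # disk triangulation (local, per station)
  fan <- cbind(rep(1L, nC), 1L + j, 1L + jn[j])
  ringTri <- NULL
  if (nR > 1) {
    kk <- rep(1:(nR - 1), each = nC)
    jj2 <- rep(j, nR - 1)
    p <- 1L + (kk - 1L) * nC + jj2
    q <- 1L + (kk - 1L) * nC + jn[jj2]
    r2 <- 1L + kk * nC + jn[jj2]
    s2 <- 1L + kk * nC + jj2
    ringTri <- rbind(cbind(p, q, r2), cbind(p, r2, s2))
  }
  disk <- rbind(fan, ringTri)

  # prisms between consecutive stations
  ndt <- nrow(disk)
  slabs <- rep(0:(nA - 2), each = ndt) * nps
  dloc <- disk[rep(seq_len(ndt), nA - 1), , drop = FALSE]
  P <- cbind(dloc + slabs, dloc + slabs + nps)
  storage.mode(P) <- "integer"
  tets <- orientTets(vv, splitPrisms(P))

  boundary <- vrhon >= 1 - 1e-12 | vstat <= rs$s[1] + 1e-12 | vstat >= rs$s[nA] - 1e-12

  volume <- new("TetraMesh", vertices = vv, tets = tets, station = vstat,
                rho = vrho, rhoNorm = vrhon, rlocal = vrl,
                axis = vax, azimuth = vaz, boundary = boundary)

  new("TubeMesh", surface = surface, volume = volume)
}
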