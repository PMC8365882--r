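# Centerline morphometry: free-knot cubic regression splines fitted to
# sampled centerline points, differential geometry (curvature, torsion),
# tortuosity (distance metric) and cross-section shape index from plane
# slicing of the lumen surface.

#' @importFrom splines splineDesign
#' @importFrom grDevices chull
#' @importFrom stats integrate
NULL

# least-squares cubic B-spline fit of all 3 coordinates on shared knots
lsSplineFit <- function(u, points, intKnots) {
  knots <- c(rep(0, 4), sort(intKnots), rep(1, 4))
  B <- splines::splineDesign(knots, u, ord = 4)
  qrB <- qr(B)
  if (qrB$rank < ncol(B)) return(NULL)  # under-determined knot layout
  coef <- qr.coef(qrB, points)
  res <- points - B %*% coef
  list(knots = knots, coef = coef, rss = sum(res^2))
}

aiccOf <- function(rss, nObs, p) {
  if (nObs - p - 1 <= 0) return(Inf)
  nObs * log(max(rss, 1e-30) / nObs) + 2 * p + 2 * p * (p + 1) / (nObs - p - 1)
}

#' Fit a free-knot cubic regression-spline centerline
#'
#' Fits per-coordinate cubic least-squares B-splines on a shared
#' chord-length parameter, yielding a continuous, noise-free analytic
#' centerline whose first three derivatives feed the curvature/torsion
#' formulas. The interior knot count is selected by a corrected-AIC
#' sweep over uniform knot layouts (0..`maxInteriorKnots`); the knot
#' positions of the selected count are then refined by Nelder-Mead from
#' the uniform start.
#'
#' @param points n x 3 matrix of sampled centerline coordinates \[mm\],
#'   n >= 8, no repeated consecutive points.
#' @param maxInteriorKnots largest interior knot count swept (default 10).
#' @param optimizeKnots refine knot positions after count selection.
#' @return a [CenterlineModel-class].
#' @export
fitCenterline <- function(points, maxInteriorKnots = 10, optimizeKnots = TRUE) {
  points <- as.matrix(points)
  if (nrow(points) < 8) stopInput("need at least 8 centerline points")
  if (ncol(points) != 3) stopInput("points must be n x 3")
  d <- rowNorm(diff(points))
  if (any(d == 0)) stopInput("duplicate consecutive centerline points (rank-deficient fit)")
  u <- c(0, cumsum(d)); u <- u / u[length(u)]
  n <- nrow(points); nObs <- 3 * n

  best <- NULL; bestAicc <- Inf; bestK <- 0L
  for (k in 0:maxInteriorKnots) {
    ik <- if (k > 0) seq_len(k) / (k + 1) else numeric(0)
    fit <- lsSplineFit(u, points, ik)
    if (is.null(fit)) next
    p <- 3 * (k + 4) + k
    a <- aiccOf(fit$rss, nObs, p)
    if (a < bestAicc) { bestAicc <- a; best <- fit; bestK <- k }
  }
  if (is.null(best)) stopInput("spline fit failed for every knot layout")

  if (bestK > 0 && optimizeKnots) {
    gap <- 1 / (4 * (bestK + 1))
    obj <- function(ik) {
      ik <- sort(ik)
      if (any(ik < gap) || any(ik > 1 - gap) || any(diff(ik) < gap / 2)) return(Inf)
      f <- lsSplineFit(u, points, ik)
      if (is.null(f)) return(Inf)
      f$rss
    }
    start <- seq_len(bestK) / (bestK + 1)
    opt <- optim(start, obj, method = "Nelder-Mead",
                 control = list(maxit = 100 * bestK, warn.1d.NelderMead = FALSE))
    if (is.finite(opt$value) && opt$value < best$rss)
      best <- lsSplineFit(u, points, sort(opt$par))
  }

  model <- new("CenterlineModel", knots = best$knots, coef = best$coef,
               uGrid = numeric(0), sGrid = numeric(0),
               rms = sqrt(best$rss / nObs), nInteriorKnots = as.integer(bestK))
  # arc-length lookup table
  ug <- seq(0, 1, length.out = 1024)
  sp <- rowNorm(evalCenterline(model, ug, deriv = 1))
  sg <- c(0, cumsum((sp[-1] + sp[-length(sp)]) / 2 * diff(ug)))
  model@uGrid <- ug
  model@sGrid <- sg
  validObject(model)
  model
}

#' Evaluate a centerline model or its derivatives
#' @param model a [CenterlineModel-class].
#' @param u parameter values in \[0, 1\].
#' @param deriv derivative order 0..3 (with respect to the fit parameter).
#' @return length(u) x 3 matrix \[mm\].
#' @export
evalCenterline <- function(model, u, deriv = 0) {
  u <- pmin(pmax(u, 0), 1)
  B <- splines::splineDesign(model@knots, u, ord = 4,
                             derivs = rep(as.integer(deriv), length(u)))
  B %*% model@coef
}

# map arc-length stations to parameter values
stationParams <- function(model, sTarget) {
  approx(model@sGrid, model@uGrid, xout = sTarget, rule = 2)$y
}

#' @describeIn curvatureTorsion evaluated from the spline derivatives;
#'   parametrization-invariant formulas, so no arc-length
#'   reparametrization is needed.
#' @export
setMethod("curvatureTorsion", "CenterlineModel",
  function(object, nStations = 100, endMargin = 0.05) {
    if (nStations < 10) stopParameter("nStations must be >= 10")
    L <- max(object@sGrid)
    sTarget <- seq(endMargin * L, (1 - endMargin) * L, length.out = nStations)
    uAt <- stationParams(object, sTarget)
    d1 <- evalCenterline(object, uAt, 1)
    d2 <- evalCenterline(object, uAt, 2)
    d3 <- evalCenterline(object, uAt, 3)
    cr <- rowCross(d1, d2)
    ncr <- rowNorm(cr)
    nd1 <- rowNorm(d1)
    kappa <- ncr / nd1^3
    tauMask <- ncr > 1e-8 * nd1^3
    tau <- numeric(length(kappa))
    tau[tauMask] <- rowSums(cr[tauMask, , drop = FALSE] * d3[tauMask, , drop = FALSE]) /
      ncr[tauMask]^2
    list(s = sTarget, kappa = kappa, tau = tau, tauMask = tauMask,
         kappaMean = mean(kappa),
         tauMean = if (any(tauMask)) mean(tau[tauMask]) else 0,
         torsionUndefined = !any(tauMask))
  })

#' @describeIn distanceMetric curvilinear length by adaptive quadrature
#'   of `|C'(u)|`; errors on closed curves (coincident endpoints).
#' @export
setMethod("distanceMetric", "CenterlineModel", function(object) {
  speed <- function(u) rowNorm(evalCenterline(object, u, 1))
  L <- integrate(speed, 0, 1, rel.tol = 1e-12, subdivisions = 500L)$value
  ends <- evalCenterline(object, c(0, 1), 0)
  l <- sqrt(sum((ends[2, ] - ends[1, ])^2))
  if (l < 1e-9) stopInput("endpoints coincide; DM undefined for closed curves")
  dm <- L / l
  if (dm < 1 - 1e-9) stopGeometry("computed DM < 1; corrupt centerline model")
  dm
})

# -- cross-section slicing ------------------------------------------------

# slice a triangle soup with the plane (P, that), returning 2D points of
# the connected intersection loop closest to P, or NULL
sliceLoop <- function(vertices, triangles, P, that) {
  f <- (vertices[, 1] - P[1]) * that[1] + (vertices[, 2] - P[2]) * that[2] +
    (vertices[, 3] - P[3]) * that[3]
  scale <- max(abs(f))
  f[f == 0] <- 1e-12 * max(scale, 1e-12)
  f1 <- f[triangles[, 1]]; f2 <- f[triangles[, 2]]; f3 <- f[triangles[, 3]]
  cross <- (pmin(f1, f2, f3) < 0) & (pmax(f1, f2, f3) > 0)
  if (!any(cross)) return(NULL)
  tc <- triangles[cross, , drop = FALSE]
  segA <- matrix(NA_real_, nrow(tc), 3)
  segB <- matrix(NA_real_, nrow(tc), 3)
  edgePts <- function(i, j) {
    fi <- f[tc[, i]]; fj <- f[tc[, j]]
    hit <- fi * fj < 0
    w <- fi / (fi - fj)
    pts <- vertices[tc[, i], , drop = FALSE] +
      w * (vertices[tc[, j], , drop = FALSE] - vertices[tc[, i], , drop = FALSE])
    list(hit = hit, pts = pts)
  }
  e12 <- edgePts(1, 2); e23 <- edgePts(2, 3); e31 <- edgePts(3, 1)
  for (r in seq_len(nrow(tc))) {
    got <- list()
    if (e12$hit[r]) got <- c(got, list(e12$pts[r, ]))
    if (e23$hit[r]) got <- c(got, list(e23$pts[r, ]))
    if (e31$hit[r]) got <- c(got, list(e31$pts[r, ]))
    if (length(got) >= 2) { segA[r, ] <- got[[1]]; segB[r, ] <- got[[2]] }
  }
  ok <- !is.na(segA[, 1])
  if (!any(ok)) return(NULL)
  segA <- segA[ok, , drop = FALSE]; segB <- segB[ok, , drop = FALSE]

  # connected components via endpoint keys + union-find
  keyOf <- function(m) paste(round(m[, 1], 6), round(m[, 2], 6), round(m[, 3], 6))
  keys <- c(keyOf(segA), keyOf(segB))
  ids <- match(keys, unique(keys))
  nk <- max(ids)
  parent <- seq_len(nk)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  ns <- nrow(segA)
  for (r in seq_len(ns)) {
    a <- find(ids[r]); b <- find(ids[ns + r])
    if (a != b) parent[a] <- b
  }
  comp <- vapply(ids, find, integer(1))
  pts3 <- rbind(segA, segB)
  # pick the component whose centroid is nearest the centerline point
  comps <- unique(comp)
  dbest <- Inf; pick <- comps[1]
  for (cmp in comps) {
    m <- pts3[comp == cmp, , drop = FALSE]
    ctr <- colMeans(m)
    dd <- sum((ctr - P)^2)
    if (dd < dbest) { dbest <- dd; pick <- cmp }
  }
  m <- unique(pts3[comp == pick, , drop = FALSE])
  if (nrow(m) < 3) return(NULL)
  # project to plane basis
  e1 <- if (abs(that[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- e1 - sum(e1 * that) * that; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(that[2] * e1[3] - that[3] * e1[2],
          that[3] * e1[1] - that[1] * e1[3],
          that[1] * e1[2] - that[2] * e1[1])
  rel <- sweep(m, 2, P)
  cbind(rel %*% e1, rel %*% e2)
}

# minimum caliper width and maximum diameter of a planar point set
caliperDiameters <- function(xy) {
  h <- chull(xy)
  hp <- xy[h, , drop = FALSE]
  nh <- nrow(hp)
  if (nh < 3) return(NULL)
  Dmax <- 0
  for (i in 1:(nh - 1)) {
    dd <- (hp[(i + 1):nh, 1] - hp[i, 1])^2 + (hp[(i + 1):nh, 2] - hp[i, 2])^2
    Dmax <- max(Dmax, max(dd))
  }
  dmin <- Inf
  for (i in seq_len(nh)) {
    jn <- if (i == nh) 1L else i + 1L
    e <- hp[jn, ] - hp[i, ]
    en <- sqrt(sum(e^2))
    if (en == 0) next
    perp <- c(-e[2], e[1]) / en
    proj <- (hp[, 1] - hp[i, 1]) * perp[1] + (hp[, 2] - hp[i, 2]) * perp[2]
    dmin <- min(dmin, max(proj) - min(proj))
  }
  c(d = dmin, D = sqrt(Dmax))
}

#' Cross-section shape index profile along a vessel
#'
#' At stations uniform in arc length (excluding an end margin), the lumen
#' surface is sliced with the plane normal to the centerline tangent; the
#' connected intersection loop nearest the centerline point is kept and
#' its minimum caliper width d and maximum vertex-pair diameter D give
#' `SI = d/D` in (0, 1\] (1 = circular section). Stations with no
#' intersection are skipped with a warning.
#'
#' @param surface a [TriSurface-class] lumen surface.
#' @param model a [CenterlineModel-class] (or [ParametricCurve-class],
#'   used directly as the axis).
#' @param nStations number of stations (default 100).
#' @param endMargin arc-length fraction excluded at each end (default 0.05).
#' @return list with `s`, `si` (NA where skipped), `siMean`, `nSkipped`.
#' @export
shapeIndex <- function(surface, model, nStations = 100, endMargin = 0.05) {
  if (is(model, "ParametricCurve")) {
    L <- max(model@s)
    sTarget <- seq(endMargin * L, (1 - endMargin) * L, length.out = nStations)
    Pm <- sapply(1:3, function(k) approx(model@s, model@points[, k], xout = sTarget)$y)
    # tangents from the dense polyline
    rs <- resampleCurve(model, max(64, nStations))
    Tm <- rowUnit(sapply(1:3, function(k) approx(rs$s, rs$Tg[, k], xout = sTarget)$y))
  } else {
    L <- max(model@sGrid)
    sTarget <- seq(endMargin * L, (1 - endMargin) * L, length.out = nStations)
    uAt <- stationParams(model, sTarget)
    Pm <- evalCenterline(model, uAt, 0)
    Tm <- rowUnit(evalCenterline(model, uAt, 1))
  }
  v <- surface@vertices; tr <- surface@triangles
  si <- rep(NA_real_, nStations)
  for (i in seq_len(nStations)) {
    xy <- sliceLoop(v, tr, Pm[i, ], Tm[i, ])
    if (is.null(xy)) next
    dd <- caliperDiameters(xy)
    if (is.null(dd) || dd["D"] <= 0) next
    si[i] <- dd["d"] / dd["D"]
  }
  nSkip <- sum(is.na(si))
  if (nSkip == nStations) stopInput("no station produced an intersection loop")
  if (nSkip > 0)
    warning(sprintf("%d of %d stations produced no intersection loop and were skipped",
                    nSkip, nStations))
  list(s = sTarget, si = si, siMean = mean(si, na.rm = TRUE), nSkipped = nSkip)
}

#' Full morphometry summary of one vessel
#'
#' Convenience wrapper fitting the centerline (if raw points are given)
#' and returning mean curvature, mean torsion, distance metric and mean
#' shape index.
#'
#' @param centerline n x 3 point matrix or a fitted [CenterlineModel-class].
#' @param surface optional [TriSurface-class] for the shape index.
#' @param nStations evaluation stations.
#' @param ... passed to [fitCenterline()].
#' @return list with `kappa_mean` \[1/mm\], `tau_mean` \[1/mm\], `dm`,
#'   `si_mean` (NA without a surface) and the fitted `model`.
#' @export
morphometrySummary <- function(centerline, surface = NULL, nStations = 100, ...) {
  model <- if (is(centerline, "CenterlineModel")) centerline
           else fitCenterline(as.matrix(centerline), ...)
  ct <- curvatureTorsion(model, nStations = nStations)
  dm <- distanceMetric(model)
  siM <- NA_real_
  if (!is.null(surface)) siM <- shapeIndex(surface, model, nStations = nStations)$siMean
  list(kappa_mean = ct$kappaMean, tau_mean = ct$tauMean, dm = dm,
       si_mean = siM, torsionUndefined = ct$torsionUndefined, model = model)
}
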