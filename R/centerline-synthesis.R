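# Parametric centerline generation with closed-form differential geometry.

#' Generate a parametric centerline curve
#'
#' Produces a densely sampled space curve to serve as vessel axis, with
#' closed-form curvature/torsion attached where the generating family is
#' analytic. Supported kinds:
#' \describe{
#'   \item{straight}{`params$length` \[mm\]; kappa = tau = 0.}
#'   \item{arc}{circular arc, `params$R` \[mm\] and `params$angle` \[rad\]
#'     (default pi); kappa = 1/R, tau = 0.}
#'   \item{helix}{circular helix `(a cos u, a sin u, b u)` with
#'     `params$a` \[mm\], `params$b` \[mm/rad\], `params$turns` (default 1);
#'     kappa = a/(a^2+b^2), tau = b/(a^2+b^2).}
#'   \item{perturbed-helix}{helix with a smooth sinusoidal radial
#'     modulation (`params$amplitude` \[mm\], default 0.3;
#'     `params$nWaves`, default 3); no closed forms.}
#' }
#'
#' @param kind curve family (see Details).
#' @param params named list of parameters \[mm, rad\].
#' @param resolution sample points per mm of arc length (default 2).
#' @return a [ParametricCurve-class].
#' @examples
#' cl <- makeCenterline("helix", list(a = 3, b = 4))
#' cl@exact$kappa(0)  # 3/25
#' @export
makeCenterline <- function(kind = c("straight", "arc", "helix", "perturbed-helix"),
                           params = list(), resolution = 2) {
  kind <- match.arg(kind)
  if (resolution <= 0) stopParameter("resolution must be positive")
  p <- params

  if (kind == "straight") {
    len <- p$length
    if (is.null(len) || len <= 0) stopParameter("straight curve needs length > 0")
    L <- len
    f <- function(u) cbind(u, 0 * u, 0 * u)
    umax <- len
    exact <- list(kappa = function(u) 0 * u, tau = function(u) 0 * u,
                  length = L, chord = L)
  } else if (kind == "arc") {
    R <- p$R
    ang <- if (is.null(p$angle)) pi else p$angle
    if (is.null(R) || R <= 0) stopParameter("arc needs R > 0")
    if (ang <= 0 || ang > 2 * pi) stopParameter("arc angle must be in (0, 2*pi]")
    L <- R * ang
    f <- function(u) cbind(R * cos(u), R * sin(u), 0 * u)
    umax <- ang
    exact <- list(kappa = function(u) rep(1 / R, length(u)),
                  tau = function(u) 0 * u,
                  length = L, chord = 2 * R * sin(ang / 2))
  } else if (kind == "helix") {
    a <- p$a; b <- p$b
    turns <- if (is.null(p$turns)) 1 else p$turns
    if (is.null(a) || a <= 0) stopParameter("helix needs a > 0")
    if (is.null(b) || b <= 0) stopParameter("helix needs b > 0")
    if (turns <= 0) stopParameter("helix needs turns > 0")
    umax <- 2 * pi * turns
    c2 <- a^2 + b^2
    L <- umax * sqrt(c2)
    f <- function(u) cbind(a * cos(u), a * sin(u), b * u)
    start <- f(0); end <- f(umax)
    exact <- list(kappa = function(u) rep(a / c2, length(u)),
                  tau = function(u) rep(b / c2, length(u)),
                  length = L, chord = sqrt(sum((end - start)^2)))
  } else { # perturbed-helix
    a <- p$a; b <- p$b
    turns <- if (is.null(p$turns)) 1 else p$turns
    amp <- if (is.null(p$amplitude)) 0.3 else p$amplitude
    nw <- if (is.null(p$nWaves)) 3 else p$nWaves
    phase <- if (is.null(p$phase)) 0 else p$phase
    if (is.null(a) || a <= 0 || is.null(b) || b <= 0)
      stopParameter("perturbed-helix needs a > 0 and b > 0")
    if (amp < 0 || amp >= a) stopParameter("amplitude must be in [0, a)")
    umax <- 2 * pi * turns
    f <- function(u) {
      r <- a + amp * sin(nw * u + phase)
      cbind(r * cos(u), r * sin(u), b * u)
    }
    L <- NA_real_  # set from the dense polyline below
    exact <- NULL
  }

  # estimate arc length for sampling density, then sample uniformly in u
  uDense <- seq(0, umax, length.out = 4097)
  pts <- f(uDense)
  sDense <- c(0, cumsum(rowNorm(diff(pts))))
  Lest <- sDense[length(sDense)]
  n <- max(4, ceiling(Lest * resolution) + 1)
  u <- seq(0, umax, length.out = n)
  points <- f(u)
  s <- approx(uDense, sDense, xout = u)$y
  s[1] <- 0

  new("ParametricCurve", kind = kind, params = p, u = u,
      points = points, s = s, exact = exact)
}

# Finite-difference curvature/torsion of a sampled curve (interior points).
# Used for curves without closed forms and as a discrete estimate for
# self-intersection guards.
discreteCurveGeometry <- function(points, u) {
  n <- nrow(points)
  i <- 3:(n - 2)
  h <- diff(u)
  # central differences on a (possibly uniform) grid
  d1 <- (points[i + 1, ] - points[i - 1, ]) / (u[i + 1] - u[i - 1])
  d2 <- (points[i + 1, ] - 2 * points[i, ] + points[i - 1, ]) /
    (((u[i + 1] - u[i]) * (u[i] - u[i - 1])))
  d3 <- (points[i + 2, ] - 2 * points[i + 1, ] + 2 * points[i - 1, ] - points[i - 2, ]) /
    (2 * ((u[i + 1] - u[i]))^3)
  cr <- rowCross(d1, d2)
  ncr <- rowNorm(cr)
  kappa <- ncr / rowNorm(d1)^3
  tau <- ifelse(ncr > 1e-10, rowSums(cr * d3) / ncr^2, NA_real_)
  list(idx = i, kappa = kappa, tau = tau)
}

#' @describeIn curvatureTorsion closed forms when attached, otherwise
#'   finite differences on the dense samples.
#' @export
setMethod("curvatureTorsion", "ParametricCurve",
  function(object, nStations = 100, endMargin = 0.05) {
    if (nStations < 10) stopParameter("nStations must be >= 10")
    L <- max(object@s)
    sTarget <- seq(endMargin * L, (1 - endMargin) * L, length.out = nStations)
    if (!is.null(object@exact)) {
      uAt <- approx(object@s, object@u, xout = sTarget)$y
      kappa <- object@exact$kappa(uAt)
      tau <- object@exact$tau(uAt)
      tauMask <- kappa > 1e-12
      tauMean <- if (any(tauMask)) mean(tau[tauMask]) else 0
      return(list(s = sTarget, kappa = kappa, tau = ifelse(tauMask, tau, 0),
                  tauMask = tauMask, kappaMean = mean(kappa), tauMean = tauMean,
                  torsionUndefined = !any(tauMask)))
    }
    g <- discreteCurveGeometry(object@points, object@u)
    sAt <- object@s[g$idx]
    keep <- sAt >= endMargin * L & sAt <= (1 - endMargin) * L
    kappa <- g$kappa[keep]
    tau <- g$tau[keep]
    tauMask <- !is.na(tau)
    list(s = sAt[keep], kappa = kappa, tau = ifelse(tauMask, tau, 0),
         tauMask = tauMask, kappaMean = mean(kappa),
         tauMean = if (any(tauMask)) mean(tau[tauMask]) else 0,
         torsionUndefined = !any(tauMask))
  })

#' @describeIn distanceMetric closed-form length when available,
#'   otherwise the dense polyline length.
#' @export
setMethod("distanceMetric", "ParametricCurve", function(object) {
  pts <- object@points
  chord <- sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2))
  if (chord < 1e-9) stopInput("endpoints coincide; DM undefined for closed curves")
  L <- if (!is.null(object@exact) && is.finite(object@exact$length))
    object@exact$length else max(object@s)
  L / chord
})
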