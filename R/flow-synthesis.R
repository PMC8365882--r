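# Analytic pulsatile flow and wall-shear synthesis on tube meshes, with
# closed-form vorticity/WSS ground truth where the geometry permits.

#' Construct a periodic inflow waveform
#' @param t time samples \[s\], strictly increasing from 0, within one period.
#' @param q flow rate samples \[m^3/s\].
#' @param period period T \[s\]; defaults to the last time sample.
#' @return a [FlowWaveform-class].
#' @export
flowWaveform <- function(t, q, period = max(t)) {
  if (length(t) < 2) stopInput("a waveform needs at least 2 samples")
  new("FlowWaveform", t = as.numeric(t), q = as.numeric(q), period = period)
}

#' Cardiac-like waveform multiplier
#'
#' Two-harmonic, strictly positive periodic multiplier
#' `w(t) = 1 + 0.5 sin(2 pi t/T) + 0.3 sin(4 pi t/T)` used as the default
#' pulsatility envelope (period 0.8 s). Satisfies `w(0) = w(T)` and
#' `min w = 0.2 > 0`.
#' @param period period T \[s\].
#' @return function of time returning the multiplier.
#' @export
defaultWaveform <- function(period = 0.8) {
  force(period)
  function(t) 1 + 0.5 * sin(2 * pi * t / period) + 0.3 * sin(4 * pi * t / period)
}

#' Specify an analytic pulsatile tube flow
#'
#' The velocity at a node with normalized in-plane radius `rho_n`,
#' physical radius `rho` \[m\], local axis `t` and azimuth `theta` is
#' `v(t) = w(t) * (axial(rho_n) * t + Omega * rho * theta)` with
#' `axial = U` (plug) or `U * (1 - rho_n^2)` (parabolic, centerline speed
#' U).
#'
#' @param profile `"parabolic"` or `"plug"`.
#' @param U centerline axial speed \[m/s\].
#' @param omega rigid-body swirl rate about the local axis \[rad/s\]:
#'   a scalar, or a function of the axial station s \[mm\] (axially
#'   varying swirl, e.g. sign changes produce counter-rotating helical
#'   structures; closed-form vorticity is only attached for scalar
#'   omega).
#' @param waveform periodic multiplier `w(t)`; default [defaultWaveform()].
#' @param period cardiac period T \[s\].
#' @param nTimes samples per cycle.
#' @param mu dynamic viscosity \[Pa s\] used for analytic WSS.
#' @param swirlPhase phase offset (fraction of the period) applied to the
#'   waveform scaling of the azimuthal WSS component only; a nonzero
#'   value makes the synthetic WSS direction rotate over the cycle
#'   (nonzero OSI/transWSS), zero keeps the direction fixed.
#' @return a list of class `FlowSpec`.
#' @export
flowSpec <- function(profile = c("parabolic", "plug"), U = 0.2, omega = 0,
                     waveform = NULL, period = 0.8, nTimes = 40, mu = 0.0035,
                     swirlPhase = 0) {
  profile <- match.arg(profile)
  if (period <= 0) stopParameter("period must be positive")
  if (mu <= 0) stopParameter("viscosity must be positive")
  if (nTimes < 2) stopParameter("need at least 2 time samples per cycle")
  w <- if (is.null(waveform)) defaultWaveform(period) else waveform
  if (abs(w(0) - w(period)) > 1e-9 * max(1, abs(w(0))))
    stopParameter("waveform must be periodic: w(0) must equal w(T)")
  structure(list(profile = profile, U = U, omega = omega, w = w,
                 period = period, nTimes = as.integer(nTimes), mu = mu,
                 swirlPhase = swirlPhase),
            class = "FlowSpec")
}

isStraightMesh <- function(mesh) {
  ax <- mesh@axis
  max(abs(sweep(ax, 2, ax[1, ]))) < 1e-9
}

#' Sample an analytic velocity series on a tube volume mesh
#'
#' Evaluates the [flowSpec()] velocity model at every node and time
#' sample. For straight tubes the closed-form vorticity is attached
#' (`2 Omega` axial from the rigid swirl, plus `2 U rho / R^2` azimuthal
#' for the parabolic profile in circular sections), scaled by the
#' waveform, for use as a discretization oracle.
#'
#' @param spec a `FlowSpec`.
#' @param mesh a [TetraMesh-class] from [makeTube()] (node frames required).
#' @return a [VolumeField-class].
#' @export
sampleFlow <- function(spec, mesh) {
  if (!inherits(spec, "FlowSpec")) stopParameter("spec must come from flowSpec()")
  n <- nrow(mesh@vertices)
  nt <- spec$nTimes
  times <- (0:(nt - 1)) * spec$period / nt
  wv <- spec$w(times)
  axf <- switch(spec$profile,
                plug = rep(spec$U, n),
                parabolic = spec$U * (1 - mesh@rhoNorm^2))
  rho_m <- mesh@rho * 1e-3
  omegaAt <- if (is.function(spec$omega)) spec$omega(mesh@station)
             else rep(spec$omega, n)
  base <- axf * mesh@axis + omegaAt * rho_m * mesh@azimuth
  vel <- array(0, dim = c(n, 3, nt))
  for (ti in seq_len(nt)) vel[, , ti] <- wv[ti] * base

  vortEx <- NULL
  if (!is.function(spec$omega) && isStraightMesh(mesh)) {
    circular <- diff(range(mesh@rlocal)) < 1e-9
    if (spec$profile == "plug" || circular) {
      R_m <- mesh@rlocal * 1e-3
      wb <- 2 * spec$omega * mesh@axis
      if (spec$profile == "parabolic") wb <- wb + (2 * spec$U * rho_m / R_m^2) * mesh@azimuth
      vortEx <- array(0, dim = c(n, 3, nt))
      for (ti in seq_len(nt)) vortEx[, , ti] <- wv[ti] * wb
    }
  }
  new("VolumeField", mesh = mesh, times = times, period = spec$period,
      velocity = vel, vorticityExact = vortEx)
}

#' Sample an analytic WSS vector series on a tube surface mesh
#'
#' For the parabolic profile the wall shear exerted by the axial flow is
#' `2 mu U / R_local` (centerline speed convention) in the local axis
#' direction; a synthetic swirl contribution of magnitude `mu * Omega`
#' is added along the local azimuth. Both are scaled by the waveform
#' `w(t)`. The plug profile carries no analytic wall shear and raises a
#' capability error (supply a user WSS series through [surfaceField()]
#' instead).
#'
#' @param spec a `FlowSpec` with `profile = "parabolic"`.
#' @param surface a [TriSurface-class] from [makeTube()] (frame required).
#' @return a [SurfaceField-class] \[Pa\].
#' @export
sampleWSS <- function(spec, surface) {
  if (!inherits(spec, "FlowSpec")) stopParameter("spec must come from flowSpec()")
  if (spec$profile != "parabolic")
    stopCapability("analytic WSS is only available for the parabolic profile; supply a user series")
  if (is.null(surface@frame))
    stopCapability("surface carries no local frame; supply a user WSS series")
  nt <- spec$nTimes
  times <- (0:(nt - 1)) * spec$period / nt
  wv <- spec$w(times)
  wvAz <- spec$w(times + (spec$swirlPhase %||% 0) * spec$period)
  R_m <- surface@frame$rlocal * 1e-3
  omegaAt <- if (is.function(spec$omega)) spec$omega(surface@station)
             else rep(spec$omega, nrow(surface@vertices))
  baseAx <- (2 * spec$mu * spec$U / R_m) * surface@frame$axis
  baseAz <- (spec$mu * omegaAt) * surface@frame$azimuth
  n <- nrow(surface@vertices)
  wss <- array(0, dim = c(n, 3, nt))
  for (ti in seq_len(nt)) wss[, , ti] <- wv[ti] * baseAx + wvAz[ti] * baseAz
  new("SurfaceField", surface = surface, times = times,
      period = spec$period, wss = wss)
}

#' Assemble a surface field from a user-supplied WSS series
#' @param surface a [TriSurface-class].
#' @param times time samples \[s\] starting at 0.
#' @param period period T \[s\].
#' @param wss array nodes x 3 x times \[Pa\].
#' @return a [SurfaceField-class].
#' @export
surfaceField <- function(surface, times, period, wss) {
  if (any(!is.finite(wss))) stopInput("WSS series contains non-finite values")
  new("SurfaceField", surface = surface, times = times, period = period, wss = wss)
}

#' Assemble a volume field from a user-supplied velocity series
#' @param mesh a [TetraMesh-class].
#' @param times time samples \[s\] starting at 0.
#' @param period period T \[s\].
#' @param velocity array nodes x 3 x times \[m/s\].
#' @param vorticityExact optional closed-form vorticity array \[1/s\].
#' @return a [VolumeField-class].
#' @export
volumeField <- function(mesh, times, period, velocity, vorticityExact = NULL) {
  new("VolumeField", mesh = mesh, times = times, period = period,
      velocity = velocity, vorticityExact = vorticityExact)
}

#' Inflow-rate waveform implied by a flow specification
#'
#' Q(t) = w(t) * mean axial velocity * lumen area, for an elliptical
#' section with major semi-axis `radius` and minor `ecc * radius`.
#' @param spec a `FlowSpec`.
#' @param radius major semi-axis \[mm\].
#' @param ecc minor/major ratio.
#' @return a [FlowWaveform-class] \[m^3/s\].
#' @export
inflowWaveform <- function(spec, radius, ecc = 1) {
  meanU <- if (spec$profile == "plug") spec$U else spec$U / 2
  area_m2 <- pi * (radius * 1e-3) * (ecc * radius * 1e-3)
  t <- (0:(spec$nTimes - 1)) * spec$period / spec$nTimes
  flowWaveform(t, spec$w(t) * meanU * area_m2, period = spec$period)
}

#' @describeIn waveformSummary trapezoidal cycle mean with periodic
#'   closure; peak and peak-to-peak from the samples.
#' @export
setMethod("waveformSummary", "FlowWaveform", function(waveform) {
  q <- waveform@q
  list(mean = unname(cycleIntegral(q, waveform@t, waveform@period)) / waveform@period,
       peak = max(q),
       peak_to_peak = max(q) - min(q))
})
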