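#' @import methods
NULL

setClassUnion("listOrNULL", c("list", "NULL"))
setClassUnion("arrayOrNULL", c("array", "NULL"))

#' Sampled parametric space curve with optional closed-form geometry
#'
#' Container for a densely sampled centerline curve. When the generating
#' curve has analytic curvature/torsion (straight segment, circular arc,
#' circular helix) the closed forms are attached in `exact` and serve as
#' ground truth for morphometry validation.
#'
#' @slot kind one of `"straight"`, `"arc"`, `"helix"`, `"perturbed-helix"`.
#' @slot params named list of generating parameters (mm, mm/rad).
#' @slot u parameter samples (strictly increasing).
#' @slot points n x 3 matrix of sampled coordinates \[mm\].
#' @slot s cumulative arc length at the samples \[mm\].
#' @slot exact `NULL`, or a list with functions `kappa(u)`, `tau(u)` and
#'   numbers `length`, `chord` where closed forms exist.
#' @export
setClass("ParametricCurve",
  representation(kind = "character", params = "list", u = "numeric",
                 points = "matrix", s = "numeric", exact = "listOrNULL"))

setValidity("ParametricCurve", function(object) {
  if (nrow(object@points) < 4) return("curve must have at least 4 sample points")
  if (any(diff(object@s) <= 0)) return("arc length must be strictly increasing")
  if (any(!is.finite(object@points))) return("non-finite coordinates")
  TRUE
})

#' Triangulated lumen surface
#'
#' @slot vertices n x 3 node coordinates \[mm\].
#' @slot triangles m x 3 node indices (1-based internally; files use 0-based).
#' @slot normals n x 3 outward unit normals.
#' @slot station axial arc-length station s \[mm\] per node (NA if unknown).
#' @slot frame optional list of per-node `axis` and `azimuth` direction
#'   matrices and `rlocal` wall distance \[mm\] (set by [makeTube()]).
#' @export
setClass("TriSurface",
  representation(vertices = "matrix", triangles = "matrix", normals = "matrix",
                 station = "numeric", frame = "listOrNULL"))

setValidity("TriSurface", function(object) {
  n <- nrow(object@vertices)
  if (ncol(object@vertices) != 3) return("vertices must be n x 3")
  if (ncol(object@triangles) != 3) return("triangles must be m x 3")
  if (nrow(object@triangles) > 0 &&
      (min(object@triangles) < 1 || max(object@triangles) > n))
    return("triangle indices out of range")
  if (nrow(object@normals) != n) return("one normal per node required")
  nn <- rowNorm(object@normals)
  if (any(abs(nn - 1) > 1e-6)) return("normals must be unit length (tol 1e-6)")
  TRUE
})

#' Tetrahedral lumen volume
#'
#' @slot vertices n x 3 node coordinates \[mm\].
#' @slot tets m x 4 node indices (1-based, positively oriented).
#' @slot station axial station s \[mm\] per node.
#' @slot rho in-plane distance from the centerline \[mm\] per node.
#' @slot rhoNorm normalized in-plane radius in \[0, 1\] per node.
#' @slot rlocal local wall distance along the node's ray \[mm\].
#' @slot axis n x 3 local axis (tangent) direction per node.
#' @slot azimuth n x 3 local azimuthal direction per node (zero on the axis).
#' @slot boundary logical per node, `TRUE` on the mesh boundary.
#' @export
setClass("TetraMesh",
  representation(vertices = "matrix", tets = "matrix", station = "numeric",
                 rho = "numeric", rhoNorm = "numeric", rlocal = "numeric",
                 axis = "matrix", azimuth = "matrix", boundary = "logical"))

setValidity("TetraMesh", function(object) {
  n <- nrow(object@vertices)
  if (ncol(object@tets) != 4) return("tets must be m x 4")
  if (min(object@tets) < 1 || max(object@tets) > n)
    return("tet indices out of range")
  v <- tetVolumes(object)
  if (any(v <= 0)) return("all tetrahedra must have positive volume")
  TRUE
})

#' Surface + volume mesh pair produced by the tube generator
#' @slot surface a [TriSurface-class].
#' @slot volume a [TetraMesh-class].
#' @export
setClass("TubeMesh", representation(surface = "TriSurface", volume = "TetraMesh"))

#' Time-resolved WSS vector field on a lumen surface
#'
#' @slot surface the [TriSurface-class] carrier.
#' @slot times time samples \[s\], strictly increasing, starting at 0,
#'   within one period.
#' @slot period cardiac period T \[s\].
#' @slot wss numeric array, nodes x 3 x times \[Pa\].
#' @export
setClass("SurfaceField",
  representation(surface = "TriSurface", times = "numeric",
                 period = "numeric", wss = "array"))

setValidity("SurfaceField", function(object) {
  n <- nrow(object@surface@vertices)
  d <- dim(object@wss)
  if (length(d) != 3 || d[1] != n || d[2] != 3 || d[3] != length(object@times))
    return("wss must be nodes x 3 x times")
  if (length(object@times) < 2) return("need at least 2 time samples")
  if (object@times[1] != 0) return("time samples must start at 0")
  if (any(diff(object@times) <= 0)) return("times must be strictly increasing")
  if (object@period <= 0 || object@times[length(object@times)] > object@period + 1e-12)
    return("times must lie within one period (0, T]")
  if (any(!is.finite(object@wss))) return("non-finite WSS values")
  TRUE
})

#' Time-resolved velocity field on a lumen volume
#'
#' @slot mesh the [TetraMesh-class] carrier (coordinates in mm; integrals
#'   convert to SI internally).
#' @slot times time samples \[s\] starting at 0 within one period.
#' @slot period cardiac period T \[s\].
#' @slot velocity numeric array, nodes x 3 x times \[m/s\].
#' @slot vorticityExact optional closed-form vorticity array \[1/s\]
#'   attached by the synthesizer for oracle comparisons.
#' @export
setClass("VolumeField",
  representation(mesh = "TetraMesh", times = "numeric", period = "numeric",
                 velocity = "array", vorticityExact = "arrayOrNULL"))

setValidity("VolumeField", function(object) {
  n <- nrow(object@mesh@vertices)
  d <- dim(object@velocity)
  if (length(d) != 3 || d[1] != n || d[2] != 3 || d[3] != length(object@times))
    return("velocity must be nodes x 3 x times")
  if (object@times[1] != 0) return("time samples must start at 0")
  if (any(diff(object@times) <= 0)) return("times must be strictly increasing")
  if (object@period <= 0 || object@times[length(object@times)] > object@period + 1e-12)
    return("times must lie within one period (0, T]")
  if (any(!is.finite(object@velocity))) return("non-finite velocity values")
  TRUE
})

#' Per-node scalar descriptor map on a surface or volume mesh
#'
#' @slot values per-node scalar values (0 where masked).
#' @slot mask logical; `TRUE` where the descriptor is well defined.
#' @slot name descriptor name (e.g. `"TAWSS"`).
#' @slot units physical units (e.g. `"Pa"`, `""`).
#' @export
setClass("DescriptorMap",
  representation(values = "numeric", mask = "logical",
                 name = "character", units = "character"))

setValidity("DescriptorMap", function(object) {
  if (length(object@values) != length(object@mask))
    return("values and mask lengths differ")
  if (any(!is.finite(object@values[object@mask])))
    return("non-finite values on unmasked nodes")
  TRUE
})

#' Bulk helicity descriptors over one cardiac cycle
#'
#' `h1` (net helicity) and `h2` (helicity intensity) in m/s^2; `h3`
#' (signed rotational balance) and `h4 = |h3|` dimensionless, `NA` when
#' `h2` vanishes (the defining ratios are 0/0 there).
#' @slot h1,h2,h3,h4 numeric scalars.
#' @export
setClass("HelicitySummary",
  representation(h1 = "numeric", h2 = "numeric", h3 = "numeric", h4 = "numeric"))

#' Periodic inflow waveform
#' @slot t time samples \[s\] covering one period (t\[1\] = 0).
#' @slot q flow rate \[m^3/s\].
#' @slot period period T \[s\].
#' @export
setClass("FlowWaveform",
  representation(t = "numeric", q = "numeric", period = "numeric"))

setValidity("FlowWaveform", function(object) {
  if (length(object@t) != length(object@q)) return("t and q lengths differ")
  if (length(object@t) < 2) return("need at least 2 samples")
  if (any(diff(object@t) <= 0)) return("t must be strictly increasing")
  if (object@t[1] != 0) return("t must start at 0")
  if (object@period <= 0 || object@t[length(object@t)] > object@period + 1e-12)
    return("samples must cover at most one period")
  TRUE
})

#' Free-knot cubic regression-spline centerline model
#'
#' Per-coordinate least-squares cubic B-splines sharing one optimized
#' interior knot vector on a chord-length parameter, with an arc-length
#' lookup table for station placement.
#'
#' @slot knots full (boundary-replicated) knot vector on \[0, 1\].
#' @slot coef basis x 3 coefficient matrix \[mm\].
#' @slot uGrid,sGrid dense parameter -> arc-length \[mm\] lookup table.
#' @slot rms fit residual RMS \[mm\].
#' @slot nInteriorKnots number of interior knots selected.
#' @export
setClass("CenterlineModel",
  representation(knots = "numeric", coef = "matrix", uGrid = "numeric",
                 sGrid = "numeric", rms = "numeric", nInteriorKnots = "integer"))

setValidity("CenterlineModel", function(object) {
  if (ncol(object@coef) != 3) return("coef must have 3 columns")
  if (length(object@uGrid) != length(object@sGrid)) return("grid lengths differ")
  if (any(diff(object@sGrid) < 0)) return("arc length table must be nondecreasing")
  TRUE
})

#' Species/vessel group-comparison report
#'
#' One row per descriptor x vessel type: group medians, interquartile
#' ranges, Mann-Whitney U, two-sided p-value and significance flag.
#' @slot results data.frame of per-cell results.
#' @slot alpha significance level.
#' @slot note conventions note (raw p-values, no multiplicity adjustment).
#' @export
setClass("ComparisonReport",
  representation(results = "data.frame", alpha = "numeric", note = "character"))

# ---- show methods ------------------------------------------------------

setMethod("show", "ParametricCurve", function(object) {
  cat(sprintf("ParametricCurve '%s': %d samples, length %.3f mm%s\n",
              object@kind, nrow(object@points), max(object@s),
              if (!is.null(object@exact)) " (closed-form geometry attached)" else ""))
})

setMethod("show", "TriSurface", function(object) {
  cat(sprintf("TriSurface: %d nodes, %d triangles\n",
              nrow(object@vertices), nrow(object@triangles)))
})

setMethod("show", "TetraMesh", function(object) {
  cat(sprintf("TetraMesh: %d nodes, %d tetrahedra, volume %.4g mm^3\n",
              nrow(object@vertices), nrow(object@tets), sum(tetVolumes(object))))
})

setMethod("show", "TubeMesh", function(object) {
  cat("TubeMesh\n  "); show(object@surface); cat("  "); show(object@volume)
})

setMethod("show", "SurfaceField", function(object) {
  cat(sprintf("SurfaceField: %d nodes, %d time samples over T = %g s [Pa]\n",
              nrow(object@surface@vertices), length(object@times), object@period))
})

setMethod("show", "VolumeField", function(object) {
  cat(sprintf("VolumeField: %d nodes, %d tets, %d time samples over T = %g s [m/s]%s\n",
              nrow(object@mesh@vertices), nrow(object@mesh@tets),
              length(object@times), object@period,
              if (!is.null(object@vorticityExact)) " (closed-form vorticity attached)" else ""))
})

setMethod("show", "DescriptorMap", function(object) {
  v <- object@values[object@mask]
  cat(sprintf("DescriptorMap %s [%s]: %d/%d valid nodes, range [%.4g, %.4g]\n",
              object@name, object@units, sum(object@mask), length(object@mask),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
})

setMethod("show", "HelicitySummary", function(object) {
  cat(sprintf("HelicitySummary: h1 = %.4g, h2 = %.4g m/s^2; h3 = %.4g, h4 = %.4g\n",
              object@h1, object@h2, object@h3, object@h4))
})

setMethod("show", "FlowWaveform", function(object) {
  cat(sprintf("FlowWaveform: %d samples over T = %g s, mean %.4g m^3/s\n",
              length(object@t), object@period, waveformSummary(object)$mean))
})

setMethod("show", "CenterlineModel", function(object) {
  cat(sprintf("CenterlineModel: %d interior knots, length %.3f mm, fit RMS %.3g mm\n",
              object@nInteriorKnots, max(object@sGrid), object@rms))
})

setMethod("show", "ComparisonReport", function(object) {
  cat(sprintf("ComparisonReport: %d cells at alpha = %g (%s)\n",
              nrow(object@results), object@alpha, object@note))
  print(utils::head(object@results, 10))
  if (nrow(object@results) > 10) cat("...\n")
})
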