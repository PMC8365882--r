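# Generics and simple accessors.

#' Time-averaged wall shear stress map
#'
#' Cycle average of the WSS vector magnitude,
#' \eqn{\mathrm{TAWSS} = \frac{1}{T}\int_0^T |\mathbf{WSS}|\,dt} \[Pa\].
#' @param field a [SurfaceField-class].
#' @return a [DescriptorMap-class] in Pa.
#' @export
setGeneric("tawss", function(field) standardGeneric("tawss"))

#' Oscillatory shear index map
#'
#' \eqn{\mathrm{OSI} = 0.5\,[1 - |\int_0^T \mathbf{WSS}\,dt| / \int_0^T
#' |\mathbf{WSS}|\,dt]}, in \[0, 0.5\]: 0 for a fixed-direction WSS vector,
#' 0.5 for a vector whose time mean vanishes. Nodes where
#' \eqn{\int|\mathbf{WSS}|dt} is numerically zero are masked.
#' @param field a [SurfaceField-class].
#' @return a dimensionless [DescriptorMap-class].
#' @export
setGeneric("osi", function(field) standardGeneric("osi"))

#' Relative residence time map
#'
#' \eqn{\mathrm{RRT} = [\mathrm{TAWSS}\cdot(1 - 2\,\mathrm{OSI})]^{-1}
#' = [\frac{1}{T}|\int_0^T \mathbf{WSS}\,dt|]^{-1}} \[1/Pa\], computed via
#' the mean-vector form. Nodes with vanishing cycle-mean WSS are masked
#' (RRT diverges there).
#' @param field a [SurfaceField-class].
#' @return a [DescriptorMap-class] in 1/Pa.
#' @export
setGeneric("rrt", function(field) standardGeneric("rrt"))

#' Transverse wall shear stress map
#'
#' Cycle average of the WSS component orthogonal (within the wall-tangent
#' plane) to the cycle-mean WSS direction:
#' \eqn{\mathrm{transWSS} = \frac{1}{T}\int_0^T |\mathbf{WSS}\cdot(\mathbf{n}
#' \times \hat{u}_{mean})|\,dt} with \eqn{\hat{u}_{mean}} the unit
#' time-average WSS vector and \eqn{\mathbf{n}} the outward surface normal.
#' Nodes without a defined mean direction are masked.
#' @param field a [SurfaceField-class].
#' @return a [DescriptorMap-class] in Pa.
#' @export
setGeneric("transWSS", function(field) standardGeneric("transWSS"))

#' Reduce a descriptor map to a per-vessel scalar
#'
#' Lumped node weights (one third of the incident triangle areas) weight
#' either a mean or a sort-and-accumulate weighted median over the valid
#' nodes.
#' @param map a [DescriptorMap-class].
#' @param surface the [TriSurface-class] the map lives on.
#' @param statistic `"area_weighted_mean"` (default) or
#'   `"area_weighted_median"`.
#' @return scalar summary in the map's units.
#' @export
setGeneric("surfaceSummary",
  function(map, surface, statistic = c("area_weighted_mean", "area_weighted_median"))
    standardGeneric("surfaceSummary"))

#' Vorticity reconstruction on a tetrahedral velocity field
#'
#' Per-cell P1 (linear shape function) velocity gradients, curled and
#' volume-weight averaged to the nodes, per time step. Boundary-node
#' values are lower accuracy (one-sided stencils).
#' @param field a [VolumeField-class].
#' @return array nodes x 3 x times \[1/s\].
#' @export
setGeneric("vorticity", function(field) standardGeneric("vorticity"))

#' Local normalized helicity
#'
#' \eqn{\mathrm{LNH} = \mathbf{v}\cdot\boldsymbol{\omega} /
#' (|\mathbf{v}||\boldsymbol{\omega}|) = \cos\gamma}, the cosine of the
#' angle between velocity and vorticity; positive for right-handed and
#' negative for left-handed helical flow. Near-stagnation nodes
#' (\eqn{|v||\omega|} below threshold) are set to 0 and masked.
#' @param field a [VolumeField-class].
#' @param vort optional vorticity array from [vorticity()]; recomputed if
#'   missing.
#' @return list with `lnh` (nodes x times), `mask`, and `cycleAverage`
#'   (per-node trapezoidal cycle average).
#' @export
setGeneric("lnh", function(field, vort = NULL) standardGeneric("lnh"))

#' Bulk helicity descriptors h1-h4
#'
#' Space-time averages of helicity density \eqn{\mathbf{v}\cdot\boldsymbol\omega}:
#' \eqn{h_1 = \frac{1}{TV}\int_T\int_V v\cdot\omega\,dV\,dt},
#' \eqn{h_2 = \frac{1}{TV}\int_T\int_V |v\cdot\omega|\,dV\,dt},
#' \eqn{h_3 = h_1/h_2 \in [-1,1]}, \eqn{h_4 = |h_1|/h_2 \in [0,1]}.
#' Volume integration uses cell-centroid values (mean of the 4 node
#' values) times cell volume; time integration is trapezoidal with
#' periodic closure. `h3`/`h4` are `NA` when `h2 = 0`.
#' @param field a [VolumeField-class].
#' @param vort optional precomputed vorticity array.
#' @return a [HelicitySummary-class].
#' @export
setGeneric("helicitySummary", function(field, vort = NULL) standardGeneric("helicitySummary"))

#' Inflow waveform summary
#'
#' Time-weighted (trapezoidal) cycle mean, peak (maximum), and
#' peak-to-peak (maximum minus minimum) of the inflow rate.
#' @param waveform a [FlowWaveform-class].
#' @return list with `mean`, `peak`, `peak_to_peak` \[m^3/s\].
#' @export
setGeneric("waveformSummary", function(waveform) standardGeneric("waveformSummary"))

#' Curvature and torsion profiles along a centerline
#'
#' Frenet curvature \eqn{\kappa = |C'\times C''|/|C'|^3} and torsion
#' \eqn{\tau = [(C'\times C'')\cdot C''']/|C'\times C''|^2} at stations
#' uniform in arc length, with their along-vessel means. Torsion is
#' masked where \eqn{|C'\times C''|} is numerically zero (straight
#' segments), and the mean torsion is reported as 0 with
#' `torsionUndefined = TRUE` when every station is masked.
#' @param object a [CenterlineModel-class] or [ParametricCurve-class].
#' @param nStations number of evaluation stations (>= 10).
#' @param endMargin fraction of arc length excluded at each end.
#' @return list with `s`, `kappa`, `tau`, `tauMask`, `kappaMean`
#'   \[1/mm\], `tauMean` \[1/mm\], `torsionUndefined`.
#' @export
setGeneric("curvatureTorsion",
  function(object, nStations = 100, endMargin = 0.05)
    standardGeneric("curvatureTorsion"))

#' Distance metric (tortuosity)
#'
#' Ratio \eqn{DM = L/l \ge 1} of curvilinear length L to the Euclidean
#' distance l between the centerline endpoints.
#' @param object a [CenterlineModel-class] or [ParametricCurve-class].
#' @return scalar DM.
#' @export
setGeneric("distanceMetric", function(object) standardGeneric("distanceMetric"))

# ---- accessors ---------------------------------------------------------

#' Mesh and field accessors
#'
#' Slot accessors for the core containers; user code should prefer these
#' over direct slot access.
#' @param x a package object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))
#' @rdname accessors
#' @export
setMethod("vertices", "TriSurface", function(x) x@vertices)
#' @rdname accessors
#' @export
setMethod("vertices", "TetraMesh", function(x) x@vertices)

#' @rdname accessors
#' @export
setGeneric("triangles", function(x) standardGeneric("triangles"))
#' @rdname accessors
#' @export
setMethod("triangles", "TriSurface", function(x) x@triangles)

#' @rdname accessors
#' @export
setGeneric("surfaceNormals", function(x) standardGeneric("surfaceNormals"))
#' @rdname accessors
#' @export
setMethod("surfaceNormals", "TriSurface", function(x) x@normals)

#' @rdname accessors
#' @export
setGeneric("tetrahedra", function(x) standardGeneric("tetrahedra"))
#' @rdname accessors
#' @export
setMethod("tetrahedra", "TetraMesh", function(x) x@tets)

#' @rdname accessors
#' @export
setGeneric("nodeStation", function(x) standardGeneric("nodeStation"))
#' @rdname accessors
#' @export
setMethod("nodeStation", "TriSurface", function(x) x@station)
#' @rdname accessors
#' @export
setMethod("nodeStation", "TetraMesh", function(x) x@station)

#' @rdname accessors
#' @export
setGeneric("fieldTimes", function(x) standardGeneric("fieldTimes"))
#' @rdname accessors
#' @export
setMethod("fieldTimes", "SurfaceField", function(x) x@times)
#' @rdname accessors
#' @export
setMethod("fieldTimes", "VolumeField", function(x) x@times)

#' @rdname accessors
#' @export
setGeneric("fieldPeriod", function(x) standardGeneric("fieldPeriod"))
#' @rdname accessors
#' @export
setMethod("fieldPeriod", "SurfaceField", function(x) x@period)
#' @rdname accessors
#' @export
setMethod("fieldPeriod", "VolumeField", function(x) x@period)

#' @rdname accessors
#' @export
setGeneric("wssValues", function(x) standardGeneric("wssValues"))
#' @rdname accessors
#' @export
setMethod("wssValues", "SurfaceField", function(x) x@wss)

#' @rdname accessors
#' @export
setGeneric("velocityValues", function(x) standardGeneric("velocityValues"))
#' @rdname accessors
#' @export
setMethod("velocityValues", "VolumeField", function(x) x@velocity)

#' @rdname accessors
#' @export
setGeneric("descriptorValues", function(x) standardGeneric("descriptorValues"))
#' @rdname accessors
#' @export
setMethod("descriptorValues", "DescriptorMap", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("descriptorMask", function(x) standardGeneric("descriptorMask"))
#' @rdname accessors
#' @export
setMethod("descriptorMask", "DescriptorMap", function(x) x@mask)

#' @rdname accessors
#' @export
setGeneric("tubeSurface", function(x) standardGeneric("tubeSurface"))
#' @rdname accessors
#' @export
setMethod("tubeSurface", "TubeMesh", function(x) x@surface)

#' @rdname accessors
#' @export
setGeneric("tubeVolume", function(x) standardGeneric("tubeVolume"))
#' @rdname accessors
#' @export
setMethod("tubeVolume", "TubeMesh", function(x) x@volume)

#' @rdname accessors
#' @export
setGeneric("reportTable", function(x) standardGeneric("reportTable"))
#' @rdname accessors
#' @export
setMethod("reportTable", "ComparisonReport", function(x) x@results)

#' Signed tetrahedron volumes of a mesh
#' @param mesh a [TetraMesh-class].
#' @return numeric vector of cell volumes \[mm^3\].
#' @export
tetVolumes <- function(mesh) {
  v <- mesh@vertices
  t <- mesh@tets
  a <- v[t[, 1], , drop = FALSE]
  b <- v[t[, 2], , drop = FALSE] - a
  c3 <- v[t[, 3], , drop = FALSE] - a
  d <- v[t[, 4], , drop = FALSE] - a
  rowSums(b * rowCross(c3, d)) / 6
}

#' Triangle areas of a surface mesh
#' @param surface a [TriSurface-class].
#' @return numeric vector of triangle areas \[mm^2\].
#' @export
triangleAreas <- function(surface) {
  v <- surface@vertices
  t <- surface@triangles
  e1 <- v[t[, 2], , drop = FALSE] - v[t[, 1], , drop = FALSE]
  e2 <- v[t[, 3], , drop = FALSE] - v[t[, 1], , drop = FALSE]
  rowNorm(rowCross(e1, e2)) / 2
}

#' Lumped per-node area weights (one third of incident triangle areas)
#' @param surface a [TriSurface-class].
#' @return numeric vector of node weights \[mm^2\].
#' @export
nodeAreas <- function(surface) {
  areas <- triangleAreas(surface)
  idx <- as.vector(surface@triangles)
  w <- numeric(nrow(surface@vertices))
  acc <- rowsum(rep(areas, 3), idx)
  w[as.integer(rownames(acc))] <- acc[, 1] / 3
  w
}
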