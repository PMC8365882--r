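# Near-wall WSS descriptor maps. All cycle integrals are trapezoidal on
# the (possibly non-uniform) time grid with periodic closure, and maps
# are node-based with lumped one-third area weights for the per-vessel
# reduction.

# |WSS| per node per time -> n x nt matrix
wssMagnitude <- function(field) {
  w <- field@wss
  n <- dim(w)[1]
  matrix(sqrt(w[, 1, ]^2 + w[, 2, ]^2 + w[, 3, ]^2), nrow = n)
}

# integral of |WSS| dt, per node
integralAbs <- function(field) {
  cycleIntegral(wssMagnitude(field), field@times, field@period)
}

# integral of the WSS vector dt, per node (n x 3)
integralVec <- function(field) {
  n <- dim(field@wss)[1]
  iv <- vapply(1:3, function(k)
    cycleIntegral(matrix(field@wss[, k, ], nrow = n), field@times, field@period),
    numeric(n))
  matrix(iv, nrow = n)
}

newMap <- function(values, mask, name, units) {
  values[!mask] <- 0
  new("DescriptorMap", values = values, mask = mask, name = name, units = units)
}

#' @describeIn tawss trapezoidal cycle average of the WSS magnitude.
#' @export
setMethod("tawss", "SurfaceField", function(field) {
  v <- integralAbs(field) / field@period
  newMap(v, rep(TRUE, length(v)), "TAWSS", "Pa")
})

#' @describeIn osi nodes with numerically zero `int |WSS| dt` (relative
#'   to the mesh maximum) are masked rather than evaluated 0/0; values
#'   clamped to \[0, 0.5\] against roundoff.
#' @export
setMethod("osi", "SurfaceField", function(field) {
  ia <- integralAbs(field)
  iv <- integralVec(field)
  mask <- ia > 1e-12 * max(ia)
  v <- numeric(length(ia))
  v[mask] <- 0.5 * (1 - rowNorm(iv[mask, , drop = FALSE]) / ia[mask])
  v <- pmin(pmax(v, 0), 0.5)
  newMap(v, mask, "OSI", "")
})

#' @describeIn rrt mean-vector form `T / |int WSS dt|`; nodes whose
#'   cycle-mean WSS vector is numerically zero are masked (RRT diverges).
#' @export
setMethod("rrt", "SurfaceField", function(field) {
  iv <- integralVec(field)
  m <- rowNorm(iv)
  mask <- m > 1e-12 * max(m)
  v <- numeric(length(m))
  v[mask] <- field@period / m[mask]
  newMap(v, mask, "RRT", "1/Pa")
})

#' @describeIn transWSS masked where the cycle-mean WSS direction is
#'   undefined.
#' @export
setMethod("transWSS", "SurfaceField", function(field) {
  iv <- integralVec(field)
  m <- rowNorm(iv)
  mask <- m > 1e-12 * max(m)
  uhat <- iv / ifelse(m > 0, m, 1)
  q <- rowCross(field@surface@normals, uhat)  # n x uhat_mean
  nt <- length(field@times)
  n <- nrow(q)
  proj <- matrix(0, n, nt)
  for (ti in seq_len(nt))
    proj[, ti] <- abs(rowSums(matrix(field@wss[, , ti], nrow = n) * q))
  v <- cycleIntegral(proj, field@times, field@period) / field@period
  newMap(v, mask, "transWSS", "Pa")
})

#' @describeIn surfaceSummary lumped-area weighting; masked nodes are
#'   excluded from both statistics.
#' @export
setMethod("surfaceSummary", signature(map = "DescriptorMap", surface = "TriSurface"),
  function(map, surface, statistic = c("area_weighted_mean", "area_weighted_median")) {
    statistic <- match.arg(statistic)
    if (length(map@values) != nrow(surface@vertices))
      stopInput("map and surface sizes differ")
    w <- nodeAreas(surface)
    keep <- map@mask & w > 0
    if (!any(keep)) stopInput("no valid nodes to summarize")
    x <- map@values[keep]; w <- w[keep]
    switch(statistic,
           area_weighted_mean = sum(x * w) / sum(w),
           area_weighted_median = weightedMedian(x, w))
  })
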