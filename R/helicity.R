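# Intravascular helicity descriptors: P1 vorticity reconstruction on
# tetrahedra, local normalized helicity, and the four bulk helicity
# integrals. Geometry is converted from mm to m so helicity density is
# in m/s^2-compatible units (v [m/s] . omega [1/s]).

# Per-cell constant gradients of the P1 shape functions [1/m] and cell
# volumes [m^3]; cached pieces for the curl.
p1Geometry <- function(mesh) {
  v <- mesh@vertices * 1e-3  # mm -> m
  t <- mesh@tets
  a <- v[t[, 1], , drop = FALSE]
  eb <- v[t[, 2], , drop = FALSE] - a
  ec <- v[t[, 3], , drop = FALSE] - a
  ed <- v[t[, 4], , drop = FALSE] - a
  vol6 <- rowSums(eb * rowCross(ec, ed))  # 6 * volume
  if (any(abs(vol6) < 1e-30)) stopGeometry("degenerate (zero-volume) cell in mesh")
  gb <- rowCross(ec, ed) / vol6
  gc <- rowCross(ed, eb) / vol6
  gd <- rowCross(eb, ec) / vol6
  ga <- -(gb + gc + gd)
  list(grads = list(ga, gb, gc, gd), vol = vol6 / 6)
}

# volume-weighted scatter of per-cell values to nodes
cellToNode <- function(cellVal, tets, vol, nNodes) {
  idx <- as.vector(tets)
  num <- rowsum(rep(cellVal * vol, 4), idx)
  out <- numeric(nNodes)
  out[as.integer(rownames(num))] <- num[, 1]
  out
}

#' @describeIn vorticity P1 reconstruction; exact for velocity fields
#'   linear in space.
#' @export
setMethod("vorticity", "VolumeField", function(field) {
  mesh <- field@mesh
  g <- p1Geometry(mesh)
  tets <- mesh@tets
  n <- nrow(mesh@vertices)
  nt <- length(field@times)
  den <- cellToNode(rep(1, nrow(tets)), tets, g$vol, n)
  out <- array(0, dim = c(n, 3, nt))
  for (ti in seq_len(nt)) {
    vv <- matrix(field@velocity[, , ti], nrow = n)
    # gradient of each velocity component: sum over the 4 local nodes
    gx <- matrix(0, nrow(tets), 3)  # grad v1
    gy <- matrix(0, nrow(tets), 3)
    gz <- matrix(0, nrow(tets), 3)
    for (i in 1:4) {
      vi <- vv[tets[, i], , drop = FALSE]
      gi <- g$grads[[i]]
      gx <- gx + gi * vi[, 1]
      gy <- gy + gi * vi[, 2]
      gz <- gz + gi * vi[, 3]
    }
    curl <- cbind(gz[, 2] - gy[, 3], gx[, 3] - gz[, 1], gy[, 1] - gx[, 2])
    for (k in 1:3) out[, k, ti] <- cellToNode(curl[, k], tets, g$vol, n) / den
  }
  out
})

#' Interior (non-boundary) node indices of a tetrahedral mesh
#'
#' Vorticity reconstruction is first-order accurate at interior nodes;
#' boundary nodes average one-sided cells and carry larger errors.
#' @param mesh a [TetraMesh-class].
#' @return integer vector of interior node indices.
#' @export
interiorNodes <- function(mesh) which(!mesh@boundary)

#' @describeIn lnh near-stagnation threshold
#'   `eps = 1e-12 * max|v| * max|omega|`; masked entries contribute 0.
#' @export
setMethod("lnh", "VolumeField", function(field, vort = NULL) {
  if (is.null(vort)) vort <- vorticity(field)
  n <- nrow(field@mesh@vertices)
  nt <- length(field@times)
  hd <- matrix(0, n, nt); vm <- matrix(0, n, nt); om <- matrix(0, n, nt)
  for (ti in seq_len(nt)) {
    vv <- matrix(field@velocity[, , ti], nrow = n)
    ww <- matrix(vort[, , ti], nrow = n)
    hd[, ti] <- rowSums(vv * ww)
    vm[, ti] <- rowNorm(vv)
    om[, ti] <- rowNorm(ww)
  }
  denom <- vm * om
  eps <- 1e-12 * max(vm) * max(om)
  mask <- denom > eps
  val <- matrix(0, n, nt)
  val[mask] <- hd[mask] / denom[mask]
  val <- pmin(pmax(val, -1), 1)
  cyc <- cycleIntegral(val, field@times, field@period) / field@period
  cyc <- pmin(pmax(cyc, -1), 1)  # guard summation roundoff at the limits
  list(lnh = val, mask = mask, cycleAverage = cyc)
})

#' @describeIn helicitySummary cell-centroid midpoint rule in space
#'   (exact for P1 integrands), trapezoid with periodic closure in time.
#' @export
setMethod("helicitySummary", "VolumeField", function(field, vort = NULL) {
  if (is.null(vort)) vort <- vorticity(field)
  mesh <- field@mesh
  g <- p1Geometry(mesh)
  V <- sum(g$vol)
  if (V <= 0) stopInput("zero total mesh volume")
  tets <- mesh@tets
  n <- nrow(mesh@vertices)
  nt <- length(field@times)
  int1 <- numeric(nt); int2 <- numeric(nt)
  vscale <- 0; wscale <- 0
  for (ti in seq_len(nt)) {
    vv <- matrix(field@velocity[, , ti], nrow = n)
    ww <- matrix(vort[, , ti], nrow = n)
    vscale <- max(vscale, max(abs(vv))); wscale <- max(wscale, max(abs(ww)))
    hd <- rowSums(vv * ww)
    cellHd <- (hd[tets[, 1]] + hd[tets[, 2]] + hd[tets[, 3]] + hd[tets[, 4]]) / 4
    int1[ti] <- sum(cellHd * g$vol)
    int2[ti] <- sum(abs(cellHd) * g$vol)
  }
  h1 <- unname(cycleIntegral(int1, field@times, field@period)) / (field@period * V)
  h2 <- unname(cycleIntegral(int2, field@times, field@period)) / (field@period * V)
  if (h2 > 1e-12 * vscale * wscale) {
    h3 <- h1 / h2; h4 <- abs(h1) / h2
  } else {
    # h2 numerically zero: the balance ratios are 0/0, report undefined
    h3 <- NA_real_; h4 <- NA_real_
  }
  new("HelicitySummary", h1 = h1, h2 = h2, h3 = h3, h4 = h4)
})
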