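# Internal numerical helpers shared across modules.

#' @importFrom stats approx optim quantile rnorm runif sd wilcox.test median
#' @importFrom utils read.csv write.csv
NULL

# Typed conditions so the CLI can map failures to exit codes
# (2 config, 3 format, 4 computation).
coroStop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "coroflow_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
stopParameter  <- function(fmt, ...) coroStop("coroflow_parameter_error", fmt, ...)
stopInput      <- function(fmt, ...) coroStop("coroflow_input_error", fmt, ...)
stopGeometry   <- function(fmt, ...) coroStop("coroflow_geometry_error", fmt, ...)
stopFormat     <- function(fmt, ...) coroStop("coroflow_format_error", fmt, ...)
stopConfig     <- function(fmt, ...) coroStop("coroflow_config_error", fmt, ...)
stopCapability <- function(fmt, ...) coroStop("coroflow_capability_error", fmt, ...)

# Row-wise cross product of n x 3 matrices.
rowCross <- function(a, b) {
  cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
}

rowNorm <- function(a) sqrt(rowSums(a * a))

# Normalize rows; zero rows stay zero.
rowUnit <- function(a) {
  n <- rowNorm(a)
  n[n == 0] <- 1
  a / n
}

vec3 <- function(x, y, z) c(x, y, z)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Trapezoidal weights for possibly non-uniform abscissae.
trapzWeights <- function(t) {
  nt <- length(t)
  if (nt < 2) stopInput("need at least 2 time samples for quadrature")
  dt <- diff(t)
  w <- numeric(nt)
  w[1] <- dt[1] / 2
  w[nt] <- dt[nt - 1] / 2
  if (nt > 2) w[2:(nt - 1)] <- (dt[-1] + dt[-(nt - 1)]) / 2
  w
}

# Integral over one period of a sampled periodic signal. `x` is a matrix
# with one column per time sample (or a vector). When the samples stop
# short of the period, the cycle is closed by appending the t = 0 sample
# at t = period (periodic closure).
cycleIntegral <- function(x, times, period) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  nt <- length(times)
  stopifnot(ncol(x) == nt)
  if (period - times[nt] > 1e-12 * period) {
    times <- c(times, period)
    x <- cbind(x, x[, 1])
  }
  drop(x %*% trapzWeights(times))
}

# Weighted lower median: smallest value whose cumulative weight reaches
# half the total (sort-and-accumulate convention).
weightedMedian <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  x[which(cw >= sum(w) / 2)[1]]
}

# Deterministic hash of a configuration-like object (used to stamp outputs).
configHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE), f)
  unname(tools::md5sum(f))
}

# Rotation matrix mapping unit vector `a` onto unit vector `b`.
rotationBetween <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (cth < -1 + 1e-12) {
    # opposite vectors: rotate pi about any axis orthogonal to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- p - sum(p * a) * a
    v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + cth)
}
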