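# Shared builders for synthetic meshes and fields.

straightTube <- function(length = 10, radius = 2, ecc = 1,
                         nCirc = 12, nAxial = 6, nRadial = 3) {
  makeTube(tubeSpec(makeCenterline("straight", list(length = length)),
                    radius = radius, eccentricity = ecc,
                    nCirc = nCirc, nAxial = nAxial, nRadial = nRadial))
}

# WSS field where every node carries the same vector history w(t).
# vecFun: function(t) -> length-3 vector
uniformWSSField <- function(surface, vecFun, nt = 16, period = 1) {
  n <- nrow(vertices(surface))
  times <- (0:(nt - 1)) * period / nt
  w <- array(0, dim = c(n, 3, nt))
  for (ti in seq_len(nt)) w[, , ti] <- matrix(vecFun(times[ti]), n, 3, byrow = TRUE)
  surfaceField(surface, times, period, w)
}

unitWaveform <- function(t) rep(1, length(t))

randomRotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

rotateSurface <- function(surface, R, shift = c(0, 0, 0)) {
  fr <- surface@frame
  if (!is.null(fr)) {
    fr$axis <- fr$axis %*% t(R)
    fr$azimuth <- fr$azimuth %*% t(R)
  }
  new("TriSurface",
      vertices = sweep(surface@vertices %*% t(R), 2, -shift),
      triangles = surface@triangles,
      normals = surface@normals %*% t(R),
      station = surface@station, frame = fr)
}

rotateField <- function(field, R, shift = c(0, 0, 0)) {
  w <- field@wss
  for (ti in seq_along(field@times)) w[, , ti] <- w[, , ti] %*% t(R)
  surfaceField(rotateSurface(field@surface, R, shift), field@times,
               field@period, w)
}
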