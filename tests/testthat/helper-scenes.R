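# shared helpers for building small fixtures in code

rotAngle <- function(R1, R2) {
  ct <- (sum(diag(crossprod(R1, R2))) - 1) / 2
  acos(max(-1, min(1, ct)))
}

randRot <- function() {
  q <- rnorm(4)
  rotationFromQuaternion(q / sqrt(sum(q^2)))
}

randTransform <- function(scale = 1, from = "A", to = "B") {
  rigidTransform(randRot(), runif(3, -100, 100), scale = scale,
                 frameFrom = from, frameTo = to)
}

# a small desk-scale camera for unit tests
deskCamera <- function(pose = rigidTransform(frameFrom = "W", frameTo = "C"),
                       id = "cam") {
  camera(1400, 1400, 959.5, 539.5, 1920, 1080, pose = pose, id = id)
}

# random camera looking at the origin from distance d
lookAtCamera <- function(d = 900, id = "cam") {
  p <- rnorm(3); p <- d * p / sqrt(sum(p^2))
  z <- -p / d
  up <- if (abs(z[3]) > 0.99) c(0, 1, 0) else c(0, 0, 1)
  x <- c(z[2] * up[3] - z[3] * up[2], z[3] * up[1] - z[1] * up[3],
         z[1] * up[2] - z[2] * up[1])
  x <- x / sqrt(sum(x^2))
  y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  R <- rbind(x, y, z); dimnames(R) <- NULL
  camera(1400, 1400, 959.5, 539.5, 1920, 1080,
         pose = rigidTransform(R, -as.numeric(R %*% p),
                               frameFrom = "W", frameTo = "C"), id = id)
}

# brute-force silhouette boundary of a sphere: the tangency circle
# {x : |x - c| = r, (x - o).(x - c) = 0}, sampled densely and projected.
# Independent of the dual-quadric projection path.
bruteForceSilhouette <- function(m, cam, n = 1e4) {
  o <- cameraCenter(cam)
  w <- o - m@center
  d <- sqrt(sum(w^2))
  stopifnot(d > m@radius)
  w <- w / d
  a <- if (abs(w[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- c(w[2] * a[3] - w[3] * a[2], w[3] * a[1] - w[1] * a[3],
         w[1] * a[2] - w[2] * a[1])
  u <- u / sqrt(sum(u^2))
  v <- c(w[2] * u[3] - w[3] * u[2], w[3] * u[1] - w[1] * u[3],
         w[1] * u[2] - w[2] * u[1])
  ctr <- m@center + (m@radius^2 / d) * w
  rho <- m@radius * sqrt(1 - (m@radius / d)^2)
  phi <- 2 * pi * (seq_len(n) - 1) / n
  X <- sweep(outer(cos(phi), u) * rho + outer(sin(phi), v) * rho, 2, ctr, "+")
  projectPoints(cam, X)
}

registerSyntheticScene <- function(seed, mode = "rigid", scale = 1,
                                   noisePx = 0, ...) {
  scn <- generateScene(sceneConfig(seed = seed, trueScale = scale,
                                   outlineNoisePx = noisePx, ...))
  obs <- if (noisePx > 0) scn$noisyObs else scn$exactObs
  res <- registerScene(scn$markersS, detectionsFromObservations(obs),
                       scn$cameras, mode)
  list(scene = scn, result = res,
       rotErr = rotAngle(res@transform@rotation,
                         scn$truth$transform@rotation),
       transErr = sqrt(sum((res@transform@translation -
                            scn$truth$transform@translation)^2)),
       scaleErr = abs(res@scale - scale) / scale)
}
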