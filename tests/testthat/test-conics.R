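test_that("sphere quadric has the canonical form and vanishes on the surface", {
  expect_equal(sphereQuadric(sphereMarker(c(0, 0, 0), 1)), diag(c(1, 1, 1, -1)))
  Q <- sphereQuadric(sphereMarker(c(0, 0, 0), 15))
  x <- c(15, 0, 0, 1)
  expect_equal(as.numeric(t(x) %*% Q %*% x), 0)
  # oracle: expansion of |x - c|^2 - r^2 at random surface points
  set.seed(51)
  m <- sphereMarker(c(10, 20, 30), 15)
  Q <- sphereQuadric(m)
  expect_equal(Q, t(Q))
  for (i in 1:100) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    x <- c(m@center + 15 * u, 1)
    expect_lt(abs(sum(x * (Q %*% x))), 1e-9)
    # off-surface point: quadratic form equals |x-c|^2 - r^2
    p <- m@center + runif(1, 0.1, 3) * 15 * u
    expect_equal(as.numeric(t(c(p, 1)) %*% Q %*% c(p, 1)),
                 sum((p - m@center)^2) - 15^2, tolerance = 1e-9)
  }
  expect_error(sphereMarker(c(0, 0, 0), -1), "radius")
})

test_that("on-axis sphere projects to the tangent-cone circle", {
  cam <- camera(1000, 1000, 0, 0, 1000, 1000)
  m <- sphereMarker(c(0, 0, 1000), 100, frame = "W")
  p <- conicParams(projectSphere(m, cam))
  # tangent half-angle: f * r / sqrt(d^2 - r^2)
  expect_equal(p$center, c(0, 0), tolerance = 1e-9)
  expect_equal(p$semiAxes, rep(1000 * 100 / sqrt(1000^2 - 100^2), 2),
               tolerance = 1e-9)
  # every outline sample satisfies the conic identity
  co <- projectSphere(m, cam)
  expect_lt(max(abs(conicResidual(co, sampleOutline(co, 50)))), 1e-9)
})

test_that("off-axis spheres give ellipses with growing eccentricity", {
  cam <- camera(1000, 1000, 0, 0, 1000, 1000)
  ecc <- sapply(c(50, 150, 300, 500, 800), function(off) {
    p <- conicParams(projectSphere(sphereMarker(c(off, 0, 1200), 100, "W"),
                                   cam))
    expect_gt(p$semiAxes[1], p$semiAxes[2])
    # oracle: brute-force silhouette lies on the conic
    co <- projectSphere(sphereMarker(c(off, 0, 1200), 100, "W"), cam)
    sil <- bruteForceSilhouette(sphereMarker(c(off, 0, 1200), 100, "W"), cam,
                                2000)
    expect_lt(max(abs(conicResidual(co, sil))), 1e-9)
    p$semiAxes[1] / p$semiAxes[2]
  })
  expect_true(all(diff(ecc) > 0))
})

test_that("degenerate silhouettes are rejected", {
  cam <- camera(1000, 1000, 0, 0, 1000, 1000)
  expect_error(projectSphere(sphereMarker(c(0, 0, -500), 50, "W"), cam),
               "degenerate silhouette")
  expect_error(projectSphere(sphereMarker(c(0, 0, 10), 50, "W"), cam),
               "degenerate silhouette")
})

test_that("projection oracle: analytic conic matches brute-force silhouette", {
  set.seed(52)
  for (i in 1:100) {
    cam <- lookAtCamera(d = runif(1, 600, 1500))
    m <- sphereMarker(runif(3, -80, 80), runif(1, 10, 40), frame = "W")
    co <- projectSphere(m, cam)
    sil <- bruteForceSilhouette(m, cam, 100)
    expect_lt(max(abs(conicResidual(co, sil))), 1e-6)
  }
})

test_that("projection is invariant under a world-frame change", {
  set.seed(53)
  for (i in 1:20) {
    cam <- lookAtCamera()
    m <- sphereMarker(runif(3, -80, 80), 20, frame = "W")
    G <- randTransform(from = "W", to = "W2")
    camG <- camera(cam@fx, cam@fy, cam@cx, cam@cy, cam@width, cam@height,
                   pose = compose(cam@pose, invertTransform(G)), id = cam@id)
    mG <- sphereMarker(applyTransform(G, m@center), m@radius, "W2")
    expect_equal(projectSphere(m, cam)@matrix, projectSphere(mG, camG)@matrix,
                 tolerance = 1e-9)
  }
})

test_that("conic parameter conversions round-trip", {
  # canonical circle x^2 + y^2 - 100 = 0
  p <- conicParams(conic(diag(c(1, 1, -100))))
  expect_equal(p$center, c(0, 0))
  expect_equal(p$semiAxes, c(10, 10))
  expect_equal(p$angle, 0)
  # parametric -> matrix -> parametric
  p2 <- conicParams(paramsToConic(c(50, -20), c(30, 10), 0.3))
  expect_equal(p2$center, c(50, -20), tolerance = 1e-9)
  expect_equal(p2$semiAxes, c(30, 10), tolerance = 1e-9)
  expect_equal(p2$angle, 0.3, tolerance = 1e-9)
  # sampled points satisfy the conic equation of the constructed matrix
  co <- paramsToConic(c(50, -20), c(30, 10), 0.3)
  expect_lt(max(abs(conicResidual(co, sampleOutline(co, 33)))), 1e-9)
  # matrix -> params -> matrix up to normalization
  set.seed(54)
  for (i in 1:20) {
    co <- paramsToConic(runif(2, -500, 500), sort(runif(2, 5, 200),
                                                  decreasing = TRUE),
                        runif(1, -pi / 2 + 0.01, pi / 2))
    p <- conicParams(co)
    co2 <- paramsToConic(p$center, p$semiAxes, p$angle)
    expect_lt(max(abs(co@matrix - co2@matrix)), 1e-9)
  }
  expect_error(conicParams(conic(diag(c(1, -1, -1)))), "not an ellipse")
})

test_that("outline sampling is uniform in parametric angle", {
  circ <- conic(diag(c(1, 1, -1)))
  pts <- sampleOutline(circ, 4)
  expect_equal(pts, rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1)),
               tolerance = 1e-12)
  co <- paramsToConic(c(12, 7), c(40, 22), -0.7)
  pts <- sampleOutline(co, 20)
  p <- conicParams(co)
  # recover parametric angles; consecutive spacing must be 2 pi / 20
  d <- sweep(pts, 2, p$center)
  u <- cbind(cos(p$angle) * d[, 1] + sin(p$angle) * d[, 2],
             -sin(p$angle) * d[, 1] + cos(p$angle) * d[, 2])
  th <- atan2(u[, 2] / p$semiAxes[2], u[, 1] / p$semiAxes[1])
  gaps <- diff(th) %% (2 * pi)
  expect_equal(gaps, rep(2 * pi / 20, 19), tolerance = 1e-9)
  expect_error(sampleOutline(co, 3), "at least 4")
})
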