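# direct nonlinear least-squares oracle over all points (no banding, no
# trimming): independent of the iterative fit it checks
nlsSphereCenter <- function(P, radius, init) {
  obj <- function(c0) sum((sqrt(rowSums(sweep(P, 2, c0)^2)) - radius)^2)
  stats::optim(init, obj, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 500))$par
}

test_that("noiseless complete coverage recovers the centre exactly", {
  set.seed(61)
  ctr <- c(12, -30, 44)
  mesh <- sphereMesh(ctr, 15)
  fit <- fitSphere(mesh, 15, ctr + c(3, 3, 3))
  expect_true(fit@converged)
  expect_lt(sqrt(sum((fit@marker@center - ctr)^2)), 1e-9)
  expect_lt(fit@rmsResidualMm, 1e-10)
  # any init within the basin works
  for (i in 1:5) {
    fit2 <- fitSphere(mesh, 15, ctr + runif(3, -4, 4))
    expect_lt(sqrt(sum((fit2@marker@center - ctr)^2)), 1e-9)
  }
})

test_that("hemisphere coverage with scan noise matches the direct oracle", {
  set.seed(62)
  errs <- replicate(20, {
    ctr <- runif(3, -50, 50)
    P <- sampleSphereSurface(ctr, 15, 2000, sigmaMm = 0.05, hemisphere = TRUE)
    mesh <- surfaceMesh(P, frame = "S")
    fit <- fitSphere(mesh, 15, ctr + runif(3, -2, 2))
    oracle <- nlsSphereCenter(P, 15, ctr)
    c(err = sqrt(sum((fit@marker@center - ctr)^2)),
      vsOracle = sqrt(sum((fit@marker@center - oracle)^2)))
  })
  expect_lt(stats::quantile(errs["err", ], 0.95), 0.02)
  # banded fit stays close to the all-points least-squares solution
  expect_lt(max(errs["vsOracle", ]), 0.01)
})

test_that("unbiased under symmetric noise with full coverage", {
  set.seed(63)
  sig <- 0.05
  centers <- t(replicate(200, {
    P <- sampleSphereSurface(c(0, 0, 0), 15, 800, sigmaMm = sig)
    fitSphere(surfaceMesh(P), 15, runif(3, -1, 1))@marker@center
  }))
  expect_lt(max(abs(colMeans(centers))), sig / 10)
})

test_that("far-away initialization reports insufficient support", {
  mesh <- sphereMesh(c(0, 0, 0), 15)
  expect_error(fitSphere(mesh, 15, c(100, 100, 100)), "insufficient support")
})

test_that("each centre update does not increase the support-band rms", {
  set.seed(64)
  for (i in 1:10) {
    P <- sampleSphereSurface(c(0, 0, 0), 15, 1500, sigmaMm = 0.05)
    fit <- fitSphere(surfaceMesh(P), 15, runif(3, -3, 3))
    h <- fit@rmsHistory
    expect_true(all(h[, "after"] <= h[, "before"] + 1e-12))
  }
})

test_that("localizeMarkers recovers all markers of a simulated scan", {
  scn <- generateScene(sceneConfig(seed = 65, M = 10, markerRadius = 15,
                                   meshNoiseMm = 0.05))
  inits <- do.call(rbind, lapply(scn$markersS, function(m)
    m@center + c(2, -2, 1)))
  rownames(inits) <- names(scn$markersS)
  res <- localizeMarkers(scn$mesh, 15, inits)
  expect_length(res$failures, 0)
  errs <- mapply(function(m, truth)
    sqrt(sum((m@center - truth@center)^2)), res$markers, scn$markersS)
  expect_lt(max(errs), 0.02)
  expect_identical(names(res$markers), names(scn$markersS))
})

test_that("localizeMarkers edge cases", {
  mesh <- sphereMesh(c(0, 0, 0), 15)
  # empty init list
  empty <- localizeMarkers(mesh, 15, matrix(numeric(), 0, 3))
  expect_length(empty$markers, 0)
  # two inits on the same sphere violate the separation precondition
  expect_error(
    localizeMarkers(mesh, 15, rbind(a = c(0, 0, 1), b = c(1, 0, 0))),
    "separated")
  # individual failures are flagged, remaining fits returned
  inits <- rbind(good = c(1, 1, 0), bad = c(500, 500, 500))
  res <- localizeMarkers(mesh, 15, inits)
  expect_identical(res$failures, "bad")
  expect_null(res$markers$bad)
  expect_lt(sqrt(sum(res$markers$good@center^2)), 1e-6)
})
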