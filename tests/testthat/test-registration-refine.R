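perturbTransform <- function(Tr, transMm, rotRad) {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  dt <- rnorm(3); dt <- transMm * dt / sqrt(sum(dt^2))
  rigidTransform(Tr@rotation %*% rotationFromAxisAngle(rotRad * ax),
                 Tr@translation + dt, scale = Tr@scale,
                 frameFrom = Tr@frameFrom, frameTo = Tr@frameTo)
}

test_that("noise-free refinement recovers truth from a perturbed init", {
  set.seed(91)
  scn <- generateScene(sceneConfig(seed = 91))
  truth <- scn$truth$transform
  Tin <- perturbTransform(truth, 5, 2 * pi / 180)
  res <- refineRegistration(scn$exactObs, Tin, "rigid")
  expect_true(res@converged)
  expect_lt(res@finalCost, 1e-18)
  expect_lt(rotAngle(res@transform@rotation, truth@rotation), 1e-8)
  expect_lt(sqrt(sum((res@transform@translation - truth@translation)^2)),
            1e-6)
  expect_lte(res@finalCost, res@initialCost)
})

test_that("similarity mode recovers a true scale of 1.5 exactly", {
  set.seed(92)
  scn <- generateScene(sceneConfig(seed = 92, trueScale = 1.5))
  truth <- scn$truth$transform
  Tin <- perturbTransform(truth, 5, 1 * pi / 180)
  Tin@scale <- 1.4   # perturb the scale too
  res <- refineRegistration(scn$exactObs, Tin, "similarity")
  expect_lt(abs(res@scale - 1.5), 1e-6)
  expect_lt(rotAngle(res@transform@rotation, truth@rotation), 1e-7)
})

test_that("starting at the optimum terminates immediately", {
  scn <- generateScene(sceneConfig(seed = 93))
  res <- refineRegistration(scn$exactObs, scn$truth$transform, "rigid")
  expect_lte(res@nIterations, 2L)
  expect_lt(res@finalCost, 1e-20)
  expect_lt(sqrt(sum((res@transform@translation -
                      scn$truth$transform@translation)^2)), 1e-9)
})

test_that("analytic Jacobian matches finite differences at random states", {
  set.seed(94)
  scn <- generateScene(sceneConfig(seed = 94, M = 4, N = 2, L = 8,
                                   nControl = 0))
  blocks <- sphereg:::obsBlocks(scn$exactObs)
  R0 <- scn$truth$transform@rotation
  for (i in 1:50) {
    p <- c(rnorm(3, sd = 0.02), scn$truth$transform@translation + rnorm(3, sd = 3),
           rnorm(1, sd = 0.05))
    Ja <- sphereg:::conicObjective(p, blocks, R0, 1, TRUE,
                                   jacobian = TRUE)$jacobian
    f <- function(p) sphereg:::conicObjective(p, blocks, R0, 1,
                                              TRUE)$residuals
    # fourth-order stencil keeps finite-difference round-off below the
    # comparison tolerance
    Jn <- sapply(1:7, function(k) {
      h <- 1e-3
      e <- rep(0, 7); e[k] <- h
      (f(p - 2 * e) - 8 * f(p - e) + 8 * f(p + e) - f(p + 2 * e)) / (12 * h)
    })
    expect_lt(max(abs(Ja - Jn)) / max(abs(Jn)), 1e-6)
  }
})

test_that("gauge consistency: transforming the cameras transforms the result", {
  set.seed(95)
  scn <- generateScene(sceneConfig(seed = 95))
  truth <- scn$truth$transform
  G <- randTransform(from = "W", to = "W2")
  camsG <- lapply(scn$cameras, function(cam)
    camera(cam@fx, cam@fy, cam@cx, cam@cy, cam@width, cam@height,
           pose = compose(cam@pose, invertTransform(G)), id = cam@id))
  obsG <- observationSet(camsG, scn$markersS, scn$exactObs@entries)
  TinG <- compose(G, perturbTransform(truth, 3, 1 * pi / 180))
  resG <- refineRegistration(obsG, TinG, "rigid")
  expected <- compose(G, truth)
  expect_lt(rotAngle(resG@transform@rotation, expected@rotation), 1e-8)
  expect_lt(sqrt(sum((resG@transform@translation -
                      expected@translation)^2)), 1e-8)
})
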